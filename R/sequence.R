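#' Read a protein sequence from a single-record FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record made of
#'   the 20 standard one-letter codes (case-insensitive).
#' @return Upper-case sequence string.
#' @export
read_sequence <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA record found in ", path)
  if (length(set) > 1L)
    stop("expected a single FASTA record, found ", length(set))
  s <- toupper(as.character(set[[1]]))
  letters <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(letters), amino_acids())
  if (nchar(s) == 0L) stop("empty sequence in ", path)
  if (length(bad))
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "))
  s
}

#' The packaged histone H3.1 sequence
#'
#' The canonical 136-residue human histone H3.1 (initiator Met included),
#' the reference input of the package.  Any other sequence can be supplied
#' to the same functions via [read_sequence()].
#' @return 136-character sequence string.
#' @export
h31_sequence <- function() {
  read_sequence(system.file("extdata", "h3_1.fasta", package = "bfmsim"))
}

#' Expand a residue sequence to chain nodes (multi-grain representation)
#'
#' At grain g each residue is represented by g consecutive chain nodes, all
#' carrying the residue's type (and hence its contact-matrix row and solvent
#' coupling).  Consecutive nodes -- within and between residues -- are joined
#' by the same fluctuating-bond window.
#'
#' @param sequence Residue string.
#' @param grain 1, 2 or 3 nodes per residue.
#' @return List with `node_types` (character vector, length
#'   `grain * nchar(sequence)`), `node_residue` (1-based residue index per
#'   node), `residue_nodes` (list: node indices per residue), `grain`.
#' @examples
#' expand_sequence("MA", 2)$node_types  # "M" "M" "A" "A"
#' @export
expand_sequence <- function(sequence, grain = 1L) {
  grain <- as.integer(grain)
  if (!grain %in% 1:3) stop("grain must be 1, 2 or 3")
  letters <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters) == 0L) stop("empty sequence")
  bad <- setdiff(unique(letters), amino_acids())
  if (length(bad))
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "))
  node_types <- rep(letters, each = grain)
  node_residue <- rep(seq_along(letters), each = grain)
  list(node_types = node_types,
       node_residue = node_residue,
       residue_nodes = split(seq_along(node_types), node_residue),
       grain = grain)
}

#' Reduce a node-level profile to residue resolution
#'
#' Averages a per-node quantity over each residue's nodes; the identity at
#' grain 1.
#'
#' @param values Numeric vector (length = node count) or matrix with one
#'   column per node.
#' @param grain_map Result of [expand_sequence()].
#' @return Numeric vector (or matrix) with one entry (column) per residue.
#' @export
residue_level_reduce <- function(values, grain_map) {
  g <- grain_map$grain
  nres <- length(grain_map$residue_nodes)
  if (is.matrix(values)) {
    if (ncol(values) != nres * g) stop("profile length != node count")
    out <- sapply(grain_map$residue_nodes, function(ix)
      rowMeans(values[, ix, drop = FALSE]))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1)
    return(out)
  }
  if (length(values) != nres * g) stop("profile length != node count")
  vapply(grain_map$residue_nodes, function(ix) mean(values[ix]), numeric(1))
}
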