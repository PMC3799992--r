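#' Residue alphabet used throughout the package
#'
#' The 20 standard one-letter amino-acid codes, in alphabetical order.
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Miyazawa-Jernigan residue-residue contact matrix
#'
#' Loads the bundled Miyazawa-Jernigan (1996) contact energies
#' \eqn{\epsilon_{ij}} (RT units, all attractive), or any user-supplied
#' 20x20 symmetric table in the same TSV layout, for sensitivity studies.
#'
#' @param path Optional path to a TSV file: comment lines start with `#`,
#'   then a header row `residue <20 one-letter codes>` and 20 data rows.
#' @return A 20x20 symmetric numeric matrix with one-letter row/column names.
#' @export
mj_matrix <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mj1996_contact.tsv", package = "bfmsim")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$residue
  storage.mode(m) <- "double"
  if (nrow(m) != 20L || ncol(m) != 20L)
    stop("contact matrix must be 20x20")
  if (!isTRUE(all.equal(m, t(m))))
    stop("contact matrix must be symmetric")
  if (!setequal(rownames(m), amino_acids()))
    stop("contact matrix rows must cover the 20 standard amino acids")
  m[amino_acids(), amino_acids()]
}

#' Per-residue solvent couplings
#'
#' Loads the bundled hydropathy-derived residue-solvent couplings
#' \eqn{\epsilon_i}: the Kyte-Doolittle index divided by its maximum
#' magnitude (4.5), so \eqn{\epsilon_i \in [-1, 1]} with hydrophobic (class
#' `H`) residues positive (solvent-repulsive) and polar (`P`) / charged (`E`)
#' residues negative (solvent-attractive).  The effective residue-solvent
#' coupling in a model is \eqn{f_s \epsilon_i}.
#'
#' @param path Optional path to a TSV with columns `residue`, `class`,
#'   `eps_i` (and optionally further columns, ignored).
#' @return Data frame with columns `residue`, `class`, `eps_i`.
#' @export
hydropathy_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "solvent_coupling.tsv", package = "bfmsim")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "class", "eps_i") %in% names(tab)))
  if (!setequal(tab$residue, amino_acids()))
    stop("solvent table must cover the 20 standard amino acids")
  bad_h <- tab$class == "H" & tab$eps_i <= 0
  bad_pe <- tab$class %in% c("P", "E") & tab$eps_i >= 0
  if (any(bad_h) || any(bad_pe))
    stop("solvent couplings must be positive for class H, negative for P/E")
  tab <- tab[order(tab$residue), c("residue", "class", "eps_i")]
  rownames(tab) <- tab$residue
  tab
}

#' Assemble an interaction model
#'
#' Bundles the residue-residue contact matrix, residue-solvent couplings and
#' the Lennard-Jones parameters into one object used by the simulation
#' engine and the energy functions.
#'
#' @param fs Solvent interaction strength \eqn{f_s \ge 0} multiplying the
#'   per-residue couplings; `fs = 0` decouples the solvent entirely.
#' @param contact 20x20 symmetric contact matrix (default [mj_matrix()]).
#' @param solvent Solvent-coupling table (default [hydropathy_table()]).
#' @param sigma,r_c Lennard-Jones length and cutoff, lattice constants.
#'   The engine assumes the defaults (`sigma = 1`, `r_c = sqrt(8)`).
#' @param normalize_contact Express contact energies in units of the table's
#'   mean magnitude (default).  All energies and temperatures are then in
#'   reduced units of this characteristic residue-residue interaction
#'   energy, which places the coil-globule crossover of a mixed sequence in
#'   the working temperature window T ~ 0.01-0.04.  Set to `FALSE` to use
#'   the table's raw values as the energy unit.
#' @return An object of class `bfm_model`.
#' @export
interaction_model <- function(fs = 0, contact = mj_matrix(),
                              solvent = hydropathy_table(),
                              sigma = 1, r_c = sqrt(8),
                              normalize_contact = TRUE) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs >= 0)
  if (sigma != 1 || abs(r_c - sqrt(8)) > 1e-12)
    stop("the lattice engine supports sigma = 1, r_c = sqrt(8) only")
  aa <- amino_acids()
  contact <- contact[aa, aa]
  contact_unit <- 1
  if (isTRUE(normalize_contact)) {
    contact_unit <- mean(abs(contact))
    contact <- contact / contact_unit
  }
  solvent <- solvent[aa, ]
  structure(list(fs = fs, contact = contact, solvent = solvent,
                 eps_solv = stats::setNames(solvent$eps_i, solvent$residue),
                 sigma = sigma, r_c = r_c, contact_unit = contact_unit),
            class = "bfm_model")
}

#' @export
print.bfm_model <- function(x, ...) {
  cat("bfm_model: generalized LJ (sigma = 1, r_c = sqrt(8))\n")
  cat(sprintf("  solvent strength f_s = %g\n", x$fs))
  cat(sprintf("  contact energies: mean %.3f, range [%.2f, %.2f]\n",
              mean(x$contact), min(x$contact), max(x$contact)))
  cat(sprintf("  solvent couplings eps_i in [%.3f, %.3f]\n",
              min(x$eps_solv), max(x$eps_solv)))
  invisible(x)
}

# map residue letters to 0-based type indices for the C++ engine
.type_index <- function(letters) {
  idx <- match(letters, amino_acids()) - 1L
  if (anyNA(idx))
    stop("invalid residue letter(s): ",
         paste(unique(letters[is.na(idx)]), collapse = ", "))
  idx
}

# 20x20 matrix + 20-vector in engine (alphabetical) order
.model_arrays <- function(model) {
  list(epsPair = unname(model$contact),
       epsSolv = unname(model$eps_solv[amino_acids()]))
}
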