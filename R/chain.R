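#' Initialize a chain by random self-avoiding growth
#'
#' Grows the chain node by node with uniformly chosen admissible bond vectors
#' under the excluded-volume constraint, restarting from scratch on dead ends
#' (bounded number of restarts).  The same seed always yields the same
#' configuration.
#'
#' @param sequence Residue string (one-letter codes).
#' @param grain Nodes per residue (1, 2 or 3).
#' @param lattice A [lattice_spec()].
#' @param seed Integer seed for the growth stream.
#' @param max_restarts Abort after this many failed growth attempts.
#' @return Object of class `bfm_chain`: `positions` (wrapped) and
#'   `unwrapped` (N x 3 integer, 0-based lattice coordinates), `node_types`,
#'   `node_residue`, `sequence`, `grain`, `L`.
#' @export
initialize_chain <- function(sequence, grain = 1L, lattice = lattice_spec(),
                             seed = 1L, max_restarts = 10000L) {
  gm <- expand_sequence(sequence, grain)
  N <- length(gm$node_types)
  res <- cpp_init_chain(lattice$L, N, as.integer(seed),
                        as.integer(max_restarts))
  new_bfm_chain(res$wrapped, res$unwrapped, gm, sequence, lattice$L)
}

new_bfm_chain <- function(wrapped, unwrapped, grain_map, sequence, L) {
  structure(list(positions = wrapped, unwrapped = unwrapped,
                 node_types = grain_map$node_types,
                 node_residue = grain_map$node_residue,
                 grain_map = grain_map, sequence = sequence,
                 grain = grain_map$grain, L = as.integer(L)),
            class = "bfm_chain")
}

#' @export
print.bfm_chain <- function(x, ...) {
  cat(sprintf(
    "bfm_chain: %d residues x grain %d = %d nodes on a %d^3 lattice\n",
    nchar(x$sequence), x$grain, nrow(x$positions), x$L))
  cat(sprintf("  radius of gyration: %.3f\n", radius_of_gyration(x)))
  invisible(x)
}

#' Audit the invariants of a chain state
#'
#' Checks the bond window on every consecutive pair, pairwise excluded
#' volume (Chebyshev anchor distance >= 2), and agreement of wrapped and
#' unwrapped coordinates modulo L.
#'
#' @param chain A `bfm_chain`.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_chain <- function(chain) {
  u <- chain$unwrapped
  w <- chain$positions
  L <- chain$L
  if (!all((u - w) %% L == 0))
    stop("unwrapped and wrapped coordinates disagree modulo L")
  d <- diff(u)
  if (!all(validate_bond(d)))
    stop("inadmissible bond at position ",
         which(!validate_bond(d))[1])
  # pairwise Chebyshev distance under minimum image
  N <- nrow(w)
  for (ax in 1:3) {
    dd <- abs(outer(w[, ax], w[, ax], "-"))
    dd <- pmin(dd, L - dd)
    assign(paste0("c", ax), dd)
  }
  cheb <- pmax(get("c1"), get("c2"), get("c3"))
  diag(cheb) <- Inf
  if (any(cheb < 2))
    stop("excluded-volume violation between nodes ",
         paste(which(cheb < 2, arr.ind = TRUE)[1, ], collapse = " and "))
  invisible(TRUE)
}

#' Propose a single-node trial move
#'
#' Displaces one node by one lattice unit along a uniformly chosen axis
#' direction (the six nearest-neighbour moves) and reports geometric
#' legality: both adjacent bonds must stay inside the bond window and the
#' excluded volume must hold at the candidate.  The chain is not modified.
#'
#' @param chain A `bfm_chain`.
#' @param node Node index (1-based).
#' @param direction Optional integer 1..6 selecting +x,-x,+y,-y,+z,-z;
#'   drawn uniformly (via R's RNG) when `NULL`.
#' @return List: `candidate` (unwrapped integer triple), `legal` (logical),
#'   `direction`.
#' @export
propose_move <- function(chain, node, direction = NULL) {
  N <- nrow(chain$positions)
  stopifnot(node >= 1, node <= N)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  if (is.null(direction)) direction <- sample.int(6L, 1L)
  cand_u <- chain$unwrapped[node, ] + dirs[direction, ]
  legal <- cpp_move_legal(chain$L, chain$positions, node - 1L,
                          as.integer(cand_u %% chain$L))
  list(candidate = cand_u, legal = legal, direction = direction)
}
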