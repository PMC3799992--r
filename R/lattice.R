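#' Lattice specification
#'
#' @param L Edge length in lattice constants.  Conventional sizes are 64 for
#'   one-node, 100 for two-node and 210 for three-node residue runs.
#' @param periodic Must be `TRUE`; the engine always uses periodic boundaries
#'   with minimum-image distances.
#' @return Object of class `lattice_spec`.
#' @export
lattice_spec <- function(L = 64L, periodic = TRUE) {
  L <- as.integer(L)
  stopifnot(length(L) == 1L)
  if (L < 8L) stop("lattice edge must be at least 8 lattice constants")
  if (!isTRUE(periodic)) stop("only periodic boundaries are supported")
  structure(list(L = L, periodic = TRUE), class = "lattice_spec")
}

#' Bond-window predicate
#'
#' The covalent bond window of the bond-fluctuation chain: a bond vector is
#' admissible iff its squared length lies in \{4, 5, 6, 9, 10\}, i.e.
#' \eqn{2 \le l \le \sqrt{10}} excluding \eqn{\sqrt 8}.
#'
#' @param delta Integer vector of length 3 (one bond vector) or an n x 3
#'   integer matrix of bond vectors.
#' @return Logical (vector): admissibility of each bond vector.
#' @examples
#' validate_bond(c(2, 0, 0))   # TRUE
#' validate_bond(c(2, 2, 0))   # FALSE: squared length 8
#' @export
validate_bond <- function(delta) {
  if (is.null(dim(delta))) delta <- matrix(delta, ncol = 3)
  stopifnot(ncol(delta) == 3)
  r2 <- rowSums(delta^2)
  r2 %in% c(4, 5, 6, 9, 10)
}

#' Admissible bond vectors
#'
#' All 108 integer vectors satisfying the bond window.
#' @return 108 x 3 integer matrix.
#' @export
bond_vectors <- function() cpp_bond_vectors()

#' Interaction shell offsets
#'
#' All lattice offsets within the interaction cutoff: the 92 integer vectors
#' with \eqn{0 < |o|^2 \le 8}.
#' @return 92 x 3 integer matrix.
#' @export
interaction_shell <- function() cpp_shell_offsets()

#' Generalized Lennard-Jones pair kernel
#'
#' \deqn{U = |\epsilon| (\sigma^2/r^2)^6 + \epsilon (\sigma^2/r^2)^3}
#' with \eqn{\sigma = 1}: the hard core is always repulsive; the tail is
#' attractive iff \eqn{\epsilon < 0}.  Beyond the cutoff (\eqn{r^2 > 8}) the
#' contribution is zero by convention, handled by the callers.
#'
#' @param eps Coupling (any sign); recycled against `r2`.
#' @param r2 Positive squared distance(s), lattice units.
#' @return Numeric vector of energies.
#' @examples
#' pair_potential(-1, 1)  # 0: the two terms cancel at r = sigma
#' @export
pair_potential <- function(eps, r2) {
  if (any(r2 <= 0))
    stop("r2 must be positive (r2 = 0 signals an excluded-volume breach)")
  x3 <- (1 / r2)^3
  ifelse(r2 > 8, 0, abs(eps) * x3^2 + eps * x3)
}
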