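#' Deterministic test fixtures with analytic expectations
#'
#' Generates the small synthetic systems used to validate the observable
#' pipeline: sequences for the simulator and point sets with known geometry
#' for the structure-factor machinery.
#'
#' Kinds:
#' \describe{
#'   \item{homopolymer}{`n` copies of one residue; `params$residue`
#'     (default "A").  The 2-mer is the enumerable Boltzmann test system.}
#'   \item{random_seq}{Random sequence of length `n` (seeded).}
#'   \item{rod}{`n` collinear points spaced `a`; known
#'     \eqn{R_g = a\sqrt{(n^2-1)/12}} and \eqn{D_e = 1}.}
#'   \item{gaussian_chain}{Random walk of `n` Gaussian steps of RMS length
#'     `b`; \eqn{D_e = 2} at intermediate q.}
#'   \item{sphere_cloud}{`n` points uniform in a ball of radius `R`;
#'     \eqn{D_e = 3} for q inside the sphere scale, continuum
#'     \eqn{R_g = R\sqrt{3/5}}.}
#' }
#'
#' @param kind One of the kinds above.
#' @param params Named list of kind-specific parameters (all have defaults).
#' @param seed Integer seed.
#' @return Object of class `bfm_fixture`: `kind`, `params`, `sequence` or
#'   `points`, and an `expected` list (analytic values and, for point sets,
#'   the recommended structure-factor fit window).
#' @export
make_fixture <- function(kind = c("homopolymer", "random_seq", "rod",
                                  "gaussian_chain", "sphere_cloud"),
                         params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- function(name, default) params[[name]] %||% default
  fx <- switch(kind,
    homopolymer = {
      n <- p("n", 2L); res <- p("residue", "A")
      stopifnot(n >= 1, res %in% amino_acids())
      list(sequence = paste(rep(res, n), collapse = ""),
           expected = list(n_nodes = n))
    },
    random_seq = {
      n <- p("n", 20L)
      stopifnot(n >= 1)
      s <- .with_seed(seed, paste(sample(amino_acids(), n, replace = TRUE),
                                  collapse = ""))
      list(sequence = s, expected = list(n_nodes = n))
    },
    rod = {
      n <- p("n", 100L); a <- p("a", 2)
      pts <- cbind(a * (seq_len(n) - 1), 0, 0)
      # 1/q regime: well above the rod length, well below the point spacing
      list(points = pts,
           expected = list(rg = a * sqrt((n^2 - 1) / 12), De = 1,
                           window = c(2 * pi / (0.4 * a * n), 2 * pi / (5 * a))))
    },
    gaussian_chain = {
      n <- p("n", 200L); b <- p("b", 2.5)
      pts <- .with_seed(seed,
        apply(matrix(stats::rnorm(3 * n, sd = b / sqrt(3)), ncol = 3), 2,
              cumsum))
      rg_ideal <- b * sqrt(n / 6)
      list(points = pts,
           expected = list(De = 2,
                           window = c(2 * pi / rg_ideal, 2 * pi / (3 * b))))
    },
    sphere_cloud = {
      n <- p("n", 500L); R <- p("R", 10)
      pts <- .with_seed(seed, {
        u <- matrix(stats::rnorm(3 * n), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        u * R * stats::runif(n)^(1 / 3)
      })
      list(points = pts,
           expected = list(rg = R * sqrt(3 / 5), De = 3,
                           window = c(1 / R, 4 / R)))
    })
  structure(c(list(kind = kind, params = params, seed = seed), fx),
            class = "bfm_fixture")
}
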