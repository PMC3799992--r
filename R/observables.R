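#' Radius of gyration
#'
#' Root-mean-square distance of the nodes from their centroid, using
#' unwrapped coordinates.
#'
#' @param x A `bfm_chain`, or an N x 3 coordinate matrix.
#' @return Non-negative number.
#' @export
radius_of_gyration <- function(x) {
  pos <- if (inherits(x, "bfm_chain")) x$unwrapped else x
  pos <- as.matrix(pos)
  ctr <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, ctr)^2)))
}

# run S(q) directions etc. without touching the caller's RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Spherically averaged structure factor
#'
#' \deqn{S(|q|) = \frac{1}{N}\left\langle \big|\sum_j e^{i q \cdot r_j}\big|^2
#' \right\rangle} averaged over ensemble frames and `n_directions` random
#' unit directions per wave-vector magnitude (seeded, so reproducible).
#' Unwrapped coordinates are used throughout.  \eqn{S(q \to 0) \to N} and
#' `S(q) = 1` for a single node.
#'
#' @param x A `bfm_ensemble` (equilibrium-window frames of every sample are
#'   used), a single `bfm_run`, or a list of N x 3 coordinate matrices.
#' @param L Lattice edge, used for the default grid lower bound `2*pi/L`
#'   (taken from the object when available).
#' @param q Optional vector of wave-vector magnitudes; default `n_q`
#'   log-spaced values in `[2*pi/L, pi]`.
#' @param n_q Size of the default grid.
#' @param n_directions Random unit directions per magnitude.
#' @param seed Seed for the direction set.
#' @param window_fraction Fraction of the run treated as equilibration when
#'   `x` is an ensemble or run (default 0.5).
#' @return Object of class `bfm_sq`: data frame `q`, `S`, `se`, plus `N`
#'   (node count) and `rg` (mean radius of gyration of the frames used).
#' @export
structure_factor <- function(x, L = NULL, q = NULL, n_q = 32L,
                             n_directions = 64L, seed = 1L,
                             window_fraction = 0.5) {
  frames <- list()
  if (inherits(x, "bfm_ensemble")) {
    L <- L %||% x$config$lattice$L
    for (r in x$runs) {
      ix <- equilibrium_frames(r, fraction = window_fraction)
      if (is.null(r$frames)) stop("ensemble was run with store_frames = FALSE")
      frames <- c(frames, r$frames[ix])
    }
  } else if (inherits(x, "bfm_run")) {
    L <- L %||% x$chain$L
    ix <- equilibrium_frames(x, fraction = window_fraction)
    frames <- x$frames[ix]
  } else if (is.list(x)) {
    frames <- x
  } else if (is.matrix(x)) {
    frames <- list(x)
  } else stop("unsupported input")
  if (!length(frames)) stop("no frames to analyse")
  if (is.null(q)) {
    if (is.null(L)) stop("L is required to build the default q grid")
    q <- exp(seq(log(2 * pi / L), log(pi), length.out = n_q))
  }
  stopifnot(all(q > 0))
  N <- nrow(frames[[1]])

  dirs <- .with_seed(seed, {
    d <- matrix(stats::rnorm(3L * n_directions * length(q)), ncol = 3)
    d / sqrt(rowSums(d^2))
  })
  # columns: one (|q|, direction) pair each
  qvec <- dirs * rep(rep(q, each = n_directions), 3)
  acc <- matrix(0, nrow = length(frames), ncol = nrow(qvec))
  tq <- t(qvec)
  for (f in seq_along(frames)) {
    ph <- as.matrix(frames[[f]]) %*% tq
    acc[f, ] <- (colSums(cos(ph))^2 + colSums(sin(ph))^2) / N
  }
  grp <- rep(seq_along(q), each = n_directions)
  Sq <- tapply(colMeans(acc), grp, mean)
  n_eff <- nrow(acc) * n_directions
  se <- tapply(seq_len(ncol(acc)), grp, function(ix) {
    v <- as.vector(acc[, ix])
    stats::sd(v) / sqrt(length(v))
  })
  rg <- mean(vapply(frames, radius_of_gyration, numeric(1)))
  structure(list(profile = data.frame(q = q, S = as.numeric(Sq),
                                      se = as.numeric(se)),
                 N = N, rg = rg, n_directions = n_directions,
                 n_frames = length(frames)),
            class = "bfm_sq")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bfm_sq <- function(x, ...) {
  cat(sprintf(
    "bfm_sq: S(q) on %d magnitudes, %d frames x %d directions, N = %d\n",
    nrow(x$profile), x$n_frames, x$n_directions, x$N))
  cat(sprintf("  S(q_min) = %.2f (N = %d), <R_g> of frames = %.3f\n",
              x$profile$S[1], x$N, x$rg))
  invisible(x)
}

#' Effective dimension from a structure-factor power law
#'
#' Least-squares slope of \eqn{\log S} vs \eqn{\log q} over a window; if
#' \eqn{S(q) \propto q^{-1/\nu}} the magnitude of the slope is the effective
#' dimension \eqn{D_e \approx 1/\nu} (about 1 for a rod, 1.76 for a
#' self-avoiding coil, 2 for an ideal chain, 3 for a compact globule).  The
#' default window covers the spread of the radius of gyration: length scales
#' from `lambda_min` up to twice the radius of gyration, i.e.
#' \eqn{q \in [\pi / R_g, 2\pi/\lambda_{\min}]}.  `lambda_min` defaults to
#' 10 lattice constants (about four bond lengths): below that scale the
#' discrete chain's correlation hole and node size contaminate the power
#' law.
#'
#' @param sq A `bfm_sq`.
#' @param window Optional `c(q_lo, q_hi)` overriding the default.
#' @param rg Radius of gyration for the default window (taken from `sq` if
#'   missing).
#' @param lambda_min Smallest length scale of the default window (lattice
#'   constants).
#' @return Object of class `bfm_defit`: `De`, `se`, `window`, `n_points`,
#'   `slope`.
#' @export
fit_effective_dimension <- function(sq, window = NULL, rg = NULL,
                                    lambda_min = 10) {
  prof <- sq$profile
  if (is.null(window)) {
    rg <- rg %||% sq$rg
    window <- c(2 * pi / (2 * rg), 2 * pi / lambda_min)
  }
  stopifnot(length(window) == 2L, window[1] < window[2])
  sel <- prof$q >= window[1] & prof$q <= window[2]
  if (sum(sel) < 4L)
    stop("fit window contains fewer than 4 grid points")
  if (any(prof$S[sel] <= 0)) stop("non-positive S(q) inside fit window")
  fit <- stats::lm(log(S) ~ log(q), data = prof[sel, ])
  sl <- unname(stats::coef(fit)[2])
  se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
  structure(list(De = abs(sl), se = se, slope = sl, window = window,
                 n_points = sum(sel)),
            class = "bfm_defit")
}

#' @export
print.bfm_defit <- function(x, ...) {
  cat(sprintf("D_e = %.3f +/- %.3f  (|slope| of log S vs log q, %d points, q in [%.3f, %.3f])\n",
              x$De, x$se, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' RMS displacement of the chain center of mass
#'
#' \eqn{R_c(t) = \sqrt{\langle |COM(t) - COM(0)|^2 \rangle}} from unwrapped
#' center-of-mass trajectories, with the asymptotic exponent from a log-log
#' fit (0.5 for normal diffusion, 1 for ballistic motion).  By default the
#' average runs over all time origins (stationary increments), a
#' variance-reduced version of the fixed-origin definition; set
#' `time_origins = FALSE` for the plain t = 0 origin.
#'
#' @param x A `bfm_ensemble`, or a list of data frames/matrices of COM
#'   trajectories with columns x, y, z sampled at a fixed interval.
#' @param dt Time between recorded COM points (taken from the object when
#'   available).
#' @param time_origins Average over all origins (default) or only t = 0.
#' @param fit_range Fraction of the maximum lag used for the exponent fit,
#'   `c(lo, hi)`.
#' @return Object of class `bfm_rc`: data frame `t`, `rc`, the fitted
#'   `exponent` with `se`, and the fit window.
#' @export
rms_com_displacement <- function(x, dt = NULL, time_origins = TRUE,
                                 fit_range = c(0.02, 0.25)) {
  if (inherits(x, "bfm_ensemble")) {
    dt <- dt %||% x$config$dump_interval
    coms <- lapply(x$runs, function(r)
      rbind(r$com0, as.matrix(r$series[, c("com_x", "com_y", "com_z")])))
  } else {
    if (is.null(dt)) stop("dt is required for raw trajectories")
    coms <- lapply(x, as.matrix)
  }
  nfr <- min(vapply(coms, nrow, integer(1)))
  if (nfr < 3L) stop("need at least two recorded frames")
  lags <- seq_len(nfr - 1L)
  msd <- vapply(lags, function(l) {
    vals <- unlist(lapply(coms, function(cm) {
      if (time_origins) {
        d <- cm[(1 + l):nfr, , drop = FALSE] -
             cm[1:(nfr - l), , drop = FALSE]
      } else {
        d <- cm[1 + l, , drop = FALSE] - cm[1, , drop = FALSE]
      }
      rowSums(d^2)
    }))
    mean(vals)
  }, numeric(1))
  tt <- lags * dt
  rc <- sqrt(msd)
  maxlag <- max(tt)
  sel <- tt >= fit_range[1] * maxlag & tt <= fit_range[2] * maxlag & rc > 0
  exponent <- se <- NA_real_
  fit_window <- c(NA_real_, NA_real_)
  if (sum(sel) >= 3) {
    fit <- stats::lm(log(rc[sel]) ~ log(tt[sel]))
    exponent <- unname(stats::coef(fit)[2])
    se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
    fit_window <- range(tt[sel])
  }
  structure(list(series = data.frame(t = tt, rc = rc),
                 exponent = exponent, se = se,
                 fit_window = fit_window, time_origins = time_origins),
            class = "bfm_rc")
}

#' @export
print.bfm_rc <- function(x, ...) {
  cat(sprintf(
    "bfm_rc: R_c(t) over %d lags; exponent %.3f +/- %.3f (fit t in [%g, %g])\n",
    nrow(x$series), x$exponent, x$se, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' Per-residue energy and mobility profiles
#'
#' Equilibrium-window ensemble averages of each residue's interaction energy
#' \eqn{\langle E_n \rangle} and mobility (accepted moves per attempt); at
#' fine grain the nodes of a residue are averaged.  The ensemble must have
#' been run with `store_node_energies = TRUE`.
#'
#' @param ensemble A `bfm_ensemble`.
#' @param window_fraction Fraction treated as equilibration (default 0.5).
#' @return Object of class `bfm_profiles`: data frame with `residue`,
#'   `code`, `energy_mean`, `energy_se`, `mobility_mean`, `mobility_se`.
#' @export
residue_profiles <- function(ensemble, window_fraction = 0.5) {
  gm <- ensemble$grain_map
  per_sample <- lapply(ensemble$runs, function(r) {
    ix <- equilibrium_frames(r, fraction = window_fraction)
    if (!length(ix)) stop("equilibrium window contains no recorded frames")
    if (is.null(r$node_energies) || !nrow(r$node_energies))
      stop("run without store_node_energies = TRUE")
    en <- colMeans(r$node_energies[ix, , drop = FALSE])
    i0 <- min(ix)
    last <- nrow(r$attempts)
    att <- r$attempts[last, ] - if (i0 > 1) r$attempts[i0 - 1, ] else 0
    acc <- r$accepts[last, ] - if (i0 > 1) r$accepts[i0 - 1, ] else 0
    mob <- ifelse(att > 0, acc / att, 0)
    cbind(energy = residue_level_reduce(en, gm),
          mobility = residue_level_reduce(mob, gm))
  })
  E <- sapply(per_sample, function(m) m[, "energy"])
  M <- sapply(per_sample, function(m) m[, "mobility"])
  if (is.null(dim(E))) { E <- matrix(E, nrow = 1); M <- matrix(M, nrow = 1) }
  se <- function(m) if (ncol(m) > 1) apply(m, 1, stats::sd) / sqrt(ncol(m))
                    else rep(NA_real_, nrow(m))
  codes <- strsplit(ensemble$sequence, "")[[1]]
  structure(list(profile = data.frame(
    residue = seq_along(codes), code = codes,
    energy_mean = rowMeans(E), energy_se = se(E),
    mobility_mean = rowMeans(M), mobility_se = se(M))),
    class = "bfm_profiles")
}

#' @export
print.bfm_profiles <- function(x, ...) {
  p <- x$profile
  cat(sprintf("bfm_profiles: %d residues\n", nrow(p)))
  cat(sprintf("  <E_n> in [%.3f, %.3f]; mobility in [%.3f, %.3f]\n",
              min(p$energy_mean), max(p$energy_mean),
              min(p$mobility_mean), max(p$mobility_mean)))
  invisible(x)
}

#' Locate the peak of a scanned curve
#'
#' Grid arg-max with an optional 3-point parabolic refinement; flags peaks
#' sitting on a grid boundary (no interior maximum).
#'
#' @param x Grid (e.g. f_s values), strictly increasing.
#' @param y Values on the grid.
#' @param refine Parabolic refinement of an interior maximum.
#' @return List: `x_max`, `y_max`, `boundary` (logical), `index`.
#' @export
locate_peak <- function(x, y, refine = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 3L, !is.unsorted(x))
  i <- which.max(y)
  boundary <- i == 1L || i == length(x)
  x_max <- x[i]
  if (!boundary && refine) {
    xs <- x[(i - 1):(i + 1)]; ys <- y[(i - 1):(i + 1)]
    fit <- stats::lm(ys ~ xs + I(xs^2))
    a <- stats::coef(fit)
    if (!is.na(a[3]) && a[3] < 0) x_max <- -a[2] / (2 * a[3])
  }
  list(x_max = unname(x_max), y_max = unname(y[i]), boundary = boundary,
       index = i)
}

#' Scan the equilibrium radius of gyration over solvent strengths
#'
#' Runs one ensemble per \eqn{f_s} value and reports
#' \eqn{\langle R_g \rangle (f_s)} with standard errors and the peak
#' location \eqn{f_{sc}} (flagged if it sits on the grid boundary).
#'
#' @param sequence Residue string.
#' @param T Temperature.
#' @param fs_grid At least 3 increasing solvent strengths.
#' @param config A [bfm_config()] template; its `T` and `fs` are overridden.
#' @param keep_ensembles Keep the full ensembles (memory-heavy).
#' @return Object of class `bfm_scan`: data frame `fs`, `rg`, `se`; `fsc`;
#'   `boundary`; `T`.
#' @export
solvent_scan <- function(sequence, T, fs_grid, config,
                         keep_ensembles = FALSE) {
  stopifnot(length(fs_grid) >= 3L, !is.unsorted(fs_grid))
  res <- lapply(fs_grid, function(fs) {
    cfg <- config
    cfg$T <- T
    cfg$fs <- fs
    run_ensemble(sequence, cfg, store_frames = FALSE)
  })
  rg <- vapply(res, `[[`, numeric(1), "rg_mean")
  se <- vapply(res, `[[`, numeric(1), "rg_se")
  pk <- locate_peak(fs_grid, rg)
  structure(list(scan = data.frame(fs = fs_grid, rg = rg, se = se),
                 fsc = pk$x_max, boundary = pk$boundary, T = T,
                 ensembles = if (keep_ensembles) res else NULL),
            class = "bfm_scan")
}

#' @export
print.bfm_scan <- function(x, ...) {
  cat(sprintf("bfm_scan: <R_g>(f_s) at T = %g over %d grid points\n",
              x$T, nrow(x$scan)))
  cat(sprintf("  f_sc = %.3f%s\n", x$fsc,
              if (x$boundary) "  [peak on grid boundary]" else ""))
  invisible(x)
}
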