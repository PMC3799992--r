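#' @export
print.bfm_run <- function(x, ...) {
  cat(sprintf("bfm_run: %d MCS at T = %g, f_s = %g (%d frames)\n",
              x$steps, x$T, x$fs, nrow(x$series)))
  cat(sprintf("  final R_g = %.3f, final E = %.4f, energy drift %.2e\n",
              utils::tail(x$series$rg, 1), x$final_energy, x$energy_drift))
  invisible(x)
}

#' Plot methods
#'
#' Base-graphics diagnostics: log-log S(q) with fitted windows, R_g(f_s)
#' scans, residue profiles, R_c(t), and per-sample R_g traces.
#'
#' @param x Object to plot.
#' @param fit Optional `bfm_defit` (or list of them) drawn over a `bfm_sq`.
#' @param ... Passed to the underlying plot call.
#' @name bfm-plots
NULL

#' @rdname bfm-plots
#' @export
plot.bfm_sq <- function(x, fit = NULL, ...) {
  p <- x$profile
  graphics::plot(p$q, p$S, log = "xy", xlab = "q", ylab = "S(q)",
                 pch = 16, ...)
  if (!is.null(fit)) {
    fits <- if (inherits(fit, "bfm_defit")) list(fit) else fit
    for (f in fits) {
      sel <- p$q >= f$window[1] & p$q <= f$window[2]
      qq <- range(p$q[sel])
      s0 <- exp(mean(log(p$S[sel])) - f$slope * mean(log(p$q[sel])))
      graphics::lines(qq, s0 * qq^f$slope, col = "red3", lwd = 2)
    }
  }
  invisible(x)
}

#' @rdname bfm-plots
#' @export
plot.bfm_scan <- function(x, ...) {
  s <- x$scan
  graphics::plot(s$fs, s$rg, type = "b", pch = 16, xlab = "f_s",
                 ylab = "<R_g>", ...)
  graphics::arrows(s$fs, s$rg - s$se, s$fs, s$rg + s$se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(v = x$fsc, lty = 2, col = "red3")
  invisible(x)
}

#' @rdname bfm-plots
#' @export
plot.bfm_profiles <- function(x, ...) {
  p <- x$profile
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(p$residue, p$energy_mean, type = "h", xlab = "residue",
                 ylab = "<E_n>", ...)
  graphics::plot(p$residue, p$mobility_mean, type = "h", xlab = "residue",
                 ylab = "mobility", ...)
  invisible(x)
}

#' @rdname bfm-plots
#' @export
plot.bfm_rc <- function(x, ...) {
  s <- x$series
  graphics::plot(s$t, s$rc, log = "xy", type = "l", xlab = "t (MCS)",
                 ylab = "R_c(t)", ...)
  invisible(x)
}

#' @rdname bfm-plots
#' @export
plot.bfm_ensemble <- function(x, ...) {
  graphics::plot(NULL, xlim = range(x$runs[[1]]$series$t),
                 ylim = range(vapply(x$runs, function(r) range(r$series$rg),
                                     numeric(2))),
                 xlab = "t (MCS)", ylab = "R_g", ...)
  for (r in x$runs) graphics::lines(r$series$t, r$series$rg,
                                    col = grDevices::grey(0.4, 0.6))
  graphics::abline(h = x$rg_mean, col = "red3", lwd = 2)
  invisible(x)
}
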