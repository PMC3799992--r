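#' Run configuration
#'
#' Collects every knob of a simulation run.  Defaults mirror the
#' conventional long-run protocol (ten million MCS); scale `steps` and
#' `samples` down for desk-scale work.
#'
#' @param T Temperature, reduced units (> 0).
#' @param fs Solvent interaction strength \eqn{f_s \ge 0}.
#' @param steps Monte Carlo steps (MCS) per sample; 1 MCS = N attempted
#'   single-node moves.
#' @param samples Number of independent replicas.
#' @param seed Base integer seed; replica i uses `seed + i - 1`.
#' @param dump_interval Record observables every this many MCS
#'   (default `steps / 100`).
#' @param audit_interval Full energy recompute + geometry audit every this
#'   many MCS (default `steps / 10`); 0 disables.
#' @param grain Nodes per residue (1, 2 or 3).
#' @param lattice A [lattice_spec()]; default edge 64 / 100 / 210 for
#'   grain 1 / 2 / 3.
#' @return Object of class `bfm_config`.
#' @export
bfm_config <- function(T = 0.02, fs = 0, steps = 1e7, samples = 100,
                       seed = 1L, dump_interval = NULL,
                       audit_interval = NULL, grain = 1L, lattice = NULL) {
  steps <- as.integer(steps)
  stopifnot(T > 0, fs >= 0, steps >= 2L, samples >= 1L)
  grain <- as.integer(grain)
  if (!grain %in% 1:3) stop("grain must be 1, 2 or 3")
  if (is.null(lattice)) lattice <- lattice_spec(c(64L, 100L, 210L)[grain])
  if (is.null(dump_interval)) dump_interval <- max(1L, steps %/% 100L)
  if (is.null(audit_interval)) audit_interval <- max(1L, steps %/% 10L)
  structure(list(T = T, fs = fs, steps = steps,
                 samples = as.integer(samples), seed = as.integer(seed),
                 dump_interval = as.integer(dump_interval),
                 audit_interval = as.integer(audit_interval),
                 grain = grain, lattice = lattice),
            class = "bfm_config")
}

#' @export
print.bfm_config <- function(x, ...) {
  cat(sprintf(
    "bfm_config: T = %g, f_s = %g, %d MCS x %d samples, grain %d, L = %d\n",
    x$T, x$fs, x$steps, x$samples, x$grain, x$lattice$L))
  invisible(x)
}

#' Run Metropolis dynamics on one chain
#'
#' Advances a chain by `steps` Monte Carlo steps.  Each attempted move picks
#' a uniform random node and one of the six unit directions, checks the bond
#' window and excluded volume first, then accepts with the Boltzmann
#' probability \eqn{\min(1, e^{-\Delta E/T})}.  Energy is tracked
#' incrementally and re-derived from scratch at every audit (drift and
#' geometry violations are reported on the result).
#'
#' @param chain A `bfm_chain` (modified copy returned inside the result).
#' @param model A `bfm_model`.
#' @param steps Number of MCS.
#' @param T Temperature, reduced units.
#' @param seed Integer seed for the move stream.
#' @param dump_interval,audit_interval Recording / audit cadence in MCS.
#' @param store_frames Keep unwrapped coordinates at every dump.
#' @param store_node_energies Record per-node energies at every dump.
#' @return Object of class `bfm_run`: `series` (data frame `t`, `rg`,
#'   `energy`, `com_x/y/z`), cumulative `attempts`/`accepts` matrices
#'   (frame x node), optional `node_energies`, `frames`, the final `chain`,
#'   `energy_drift` and `geometry_ok`.
#' @export
run_chain <- function(chain, model, steps, T, seed = 1L,
                      dump_interval = max(1L, steps %/% 100L),
                      audit_interval = max(1L, steps %/% 10L),
                      store_frames = TRUE, store_node_energies = FALSE) {
  arr <- .model_arrays(model)
  res <- cpp_run(chain$L, .type_index(chain$node_types), chain$positions,
                 chain$unwrapped, arr$epsPair, arr$epsSolv, model$fs, T,
                 as.integer(steps), as.integer(dump_interval),
                 as.integer(audit_interval), as.integer(seed),
                 store_frames, store_node_energies)
  if (!res$geometry_ok)
    stop("state audit failed: bond/excluded-volume invariant breached")
  final <- chain
  final$positions <- res$wrapped
  final$unwrapped <- res$unwrapped
  structure(list(
    series = data.frame(t = res$t, rg = res$rg, energy = res$energy,
                        com_x = res$com[, 1], com_y = res$com[, 2],
                        com_z = res$com[, 3]),
    com0 = colMeans(chain$unwrapped),
    attempts = res$attempts, accepts = res$accepts,
    node_energies = if (store_node_energies) res$node_energies else NULL,
    frames = if (store_frames) res$frames else NULL,
    chain = final, T = T, fs = model$fs, steps = as.integer(steps),
    dump_interval = as.integer(dump_interval),
    energy_drift = res$energy_drift, geometry_ok = res$geometry_ok,
    final_energy = res$final_energy, seed = as.integer(seed)),
    class = "bfm_run")
}

#' Run an ensemble of independent samples
#'
#' For each replica: a fresh seeded self-avoiding-growth initialization,
#' `config$steps` Monte Carlo steps, observables recorded every
#' `config$dump_interval`.  Equilibrium averages use the later half of the
#' run.  Identical seeds give bit-identical results.
#'
#' @param sequence Residue string (e.g. [h31_sequence()]).
#' @param config A [bfm_config()].
#' @param model Optional `bfm_model`; built from `config$fs` with the
#'   bundled tables when `NULL`.
#' @param store_frames,store_node_energies Passed to each replica run.
#' @return Object of class `bfm_ensemble`: `runs` (list of `bfm_run`),
#'   `config`, `model`, `sequence`, `grain_map`, and an equilibrium summary
#'   (`rg_mean`, `rg_se`, `energy_mean`, `energy_se`).
#' @export
run_ensemble <- function(sequence, config, model = NULL,
                         store_frames = TRUE, store_node_energies = FALSE) {
  if (is.null(model)) model <- interaction_model(fs = config$fs)
  if (model$fs != config$fs)
    stop("model$fs and config$fs disagree")
  runs <- vector("list", config$samples)
  for (i in seq_len(config$samples)) {
    seed_i <- config$seed + i - 1L
    chain <- initialize_chain(sequence, config$grain, config$lattice, seed_i)
    runs[[i]] <- tryCatch(
      run_chain(chain, model, config$steps, config$T, seed = seed_i,
                dump_interval = config$dump_interval,
                audit_interval = config$audit_interval,
                store_frames = store_frames,
                store_node_energies = store_node_energies),
      error = function(e) stop("sample ", i, " failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  eq <- lapply(runs, function(r) {
    w <- r$series$t > config$steps / 2
    c(rg = mean(r$series$rg[w]), energy = mean(r$series$energy[w]))
  })
  eq <- do.call(rbind, eq)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  structure(list(runs = runs, config = config, model = model,
                 sequence = sequence,
                 grain_map = expand_sequence(sequence, config$grain),
                 rg_samples = eq[, "rg"],
                 rg_mean = mean(eq[, "rg"]), rg_se = se(eq[, "rg"]),
                 energy_mean = mean(eq[, "energy"]),
                 energy_se = se(eq[, "energy"])),
            class = "bfm_ensemble")
}

#' Equilibrium-window frame selector
#'
#' Indices of recorded frames in the equilibrium window (later half of the
#' run by default).
#' @param run A `bfm_run`.
#' @param steps Total MCS of the run it belongs to.
#' @param fraction Fraction of the run treated as pre-equilibration
#'   (default 0.5).
#' @return Integer vector of frame indices.
#' @export
equilibrium_frames <- function(run, steps = run$steps, fraction = 0.5) {
  which(run$series$t > steps * fraction)
}

#' @export
print.bfm_ensemble <- function(x, ...) {
  cat(sprintf(
    "bfm_ensemble: %d samples of %d residues (grain %d), T = %g, f_s = %g\n",
    x$config$samples, nchar(x$sequence), x$config$grain, x$config$T,
    x$config$fs))
  cat(sprintf("  equilibrium <R_g> = %.3f +/- %.3f\n", x$rg_mean, x$rg_se))
  cat(sprintf("  equilibrium <E>   = %.3f +/- %.3f\n",
              x$energy_mean, x$energy_se))
  cat(sprintf("  max incremental-energy drift: %.2e\n",
              max(vapply(x$runs, `[[`, numeric(1), "energy_drift"))))
  invisible(x)
}
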