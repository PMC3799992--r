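#' Write a trajectory as extended XYZ
#'
#' One block per recorded frame; the element column carries the residue
#' one-letter code and the comment line carries the MCS time, temperature,
#' solvent strength and grain.
#'
#' @param run A `bfm_run` produced with `store_frames = TRUE`.
#' @param path Output file.
#' @param grain Grain level written into the comment line.
#' @export
write_xyz <- function(run, path, grain = run$chain$grain) {
  if (is.null(run$frames)) stop("run has no stored frames")
  con <- file(path, "w")
  on.exit(close(con))
  types <- run$chain$node_types
  for (i in seq_along(run$frames)) {
    fr <- run$frames[[i]]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("mcs=%d T=%g fs=%g grain=%d",
                       as.integer(run$series$t[i]), run$T, run$fs, grain), con)
    writeLines(sprintf("%s %d %d %d", types, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory written by [write_xyz()]
#'
#' @param path Input file.
#' @return List with `frames` (list of N x 3 integer matrices), `types`
#'   (element column of the first frame) and `comments`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); comments <- character(); types <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comments <- c(comments, lines[i + 1L])
    rows <- strsplit(lines[(i + 2L):(i + 1L + n)], " ")
    if (is.null(types)) types <- vapply(rows, `[[`, character(1), 1L)
    m <- t(vapply(rows, function(r) as.integer(r[2:4]), integer(3)))
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  list(frames = frames, types = types, comments = comments)
}

#' Write the per-sample observable series of an ensemble to CSV
#'
#' One file per sample: `t, rg, energy, com_x, com_y, com_z`.
#' @param ensemble A `bfm_ensemble`.
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_series_csv <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(ensemble$runs)) {
    p <- file.path(dir, sprintf("sample_%03d.csv", i))
    utils::write.csv(ensemble$runs[[i]]$series, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a structure-factor profile to CSV (`q, S, se`)
#' @param sq A `bfm_sq`.
#' @param path Output file.
#' @export
write_sq_csv <- function(sq, path) {
  utils::write.csv(sq$profile, path, row.names = FALSE)
  invisible(path)
}

#' Write residue profiles to CSV
#' @param profiles A `bfm_profiles`.
#' @param path Output file.
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(profiles$profile, path, row.names = FALSE)
  invisible(path)
}

#' Write a solvent scan to CSV (`fs, rg, se`)
#' @param scan A `bfm_scan`.
#' @param path Output file.
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(scan$scan, path, row.names = FALSE)
  invisible(path)
}

#' Write effective-dimension fits to JSON
#'
#' @param fits Named list of `bfm_defit` objects.
#' @param path Output file.
#' @export
write_fits_json <- function(fits, path) {
  out <- lapply(fits, function(f)
    list(De = f$De, se = f$se, slope = f$slope,
         window = f$window, n_points = f$n_points))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Keys mirror the arguments of [bfm_config()]; `lattice` may be given as
#' the integer edge length `L`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A [bfm_config()].
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("T", "fs", "steps", "samples", "seed", "dump_interval",
             "audit_interval", "grain", "lattice")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$lattice)) cfg$lattice <- lattice_spec(cfg$lattice)
  do.call(bfm_config, cfg)
}
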