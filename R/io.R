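# CSV / text artifacts. CSV is the canonical interchange format; every
# file starts with provenance comment lines (config hash + seed) so a run
# is checkable against its configuration.

provenance_lines <- function(hash, seed) {
  c(sprintf("# config_hash: %s", hash %||% "unknown"),
    sprintf("# seed: %s", seed %||% "unknown"))
}

write_csv_stamped <- function(d, path, hash = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(hash, seed), con)
  write.csv(d, con, row.names = FALSE)
  invisible(path)
}

read_csv_stamped <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a session dataset
#'
#' A session is stored as two CSVs next to each other: the observation
#' table `(frame, camera, marker, u, v)` and the truth table
#' `(frame, marker, x, y, z)`, plus a YAML manifest echoing the
#' generating configuration and seed.
#'
#' @param session an `fm_session`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return `write_session()`: the directory, invisibly. `read_session()`:
#'   an `fm_session`.
#' @export
write_session <- function(session, dir, stem = session$manifest$kind) {
  stopifnot(inherits(session, "fm_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- session$manifest$config_hash
  s <- session$manifest$seed
  write_csv_stamped(session$observations,
                    file.path(dir, paste0(stem, "_observations.csv")), h, s)
  write_csv_stamped(session$truth,
                    file.path(dir, paste0(stem, "_truth.csv")), h, s)
  yaml::write_yaml(session$manifest, precision = 15,
                   file.path(dir, paste0(stem, "_manifest.yaml")))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir, stem) {
  manifest <- yaml::read_yaml(file.path(dir, paste0(stem, "_manifest.yaml")))
  obs <- read_csv_stamped(file.path(dir, paste0(stem, "_observations.csv")))
  truth <- read_csv_stamped(file.path(dir, paste0(stem, "_truth.csv")))
  structure(list(observations = obs, truth = truth, manifest = manifest,
                 clock = capture_clock(manifest$frequency_hz %||% 100)),
            class = "fm_session")
}

#' Write / read a calibration
#'
#' Per-camera 3x4 projection matrices plus the systemic error and pass
#' flag, as a structured text (YAML) file.
#'
#' @param calibration an `fm_calibration`.
#' @param path output file.
#' @return `write_calibration()`: `path` invisibly; `read_calibration()`:
#'   an `fm_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "fm_calibration"))
  obj <- list(projections = lapply(calibration$P, function(P)
                as.numeric(t(P))),
              systemic_error_mm = calibration$systemic_error_mm,
              frames_used = calibration$frames_used,
              threshold = calibration$threshold, pass = calibration$pass,
              seed = calibration$seed,
              config_hash = calibration$config_hash)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- yaml::read_yaml(path)
  P <- lapply(obj$projections, function(p) matrix(as.numeric(p), 3, 4,
                                                  byrow = TRUE))
  structure(list(P = P, systemic_error_mm = obj$systemic_error_mm,
                 frames_used = obj$frames_used, threshold = obj$threshold,
                 pass = obj$pass, seed = obj$seed,
                 config_hash = obj$config_hash),
            class = "fm_calibration")
}

#' Write / read trajectories
#'
#' Long-format trajectory CSV with columns `(frame, time_s, label, x, y,
#' z, n_cameras, gap, residual_px, ...)`.
#'
#' @param traj a trajectory data.frame.
#' @param path output file.
#' @param hash,seed provenance stamps.
#' @return The path / the trajectory table.
#' @export
write_trajectories <- function(traj, path, hash = NULL, seed = NULL) {
  validate_trajectories(traj)
  write_csv_stamped(traj, path, hash, seed)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  d <- read_csv_stamped(path)
  validate_trajectories(d)
  d
}
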