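# Wand-based camera calibration by the direct linear transform (DLT), and
# the calibration quality gate: the systemic error (RMS discrepancy between
# reconstructed and known wand inter-marker distances) must be below 0.3 mm
# for a calibration to pass.

# Hartley-style conditioning: similarity transform taking the points to
# centroid 0 and mean norm sqrt(d)
conditioning_transform <- function(pts) {
  d <- ncol(pts)
  centroid <- colMeans(pts)
  centred <- sweep(pts, 2, centroid)
  scale <- sqrt(d) / mean(sqrt(rowSums(centred^2)))
  Tm <- diag(c(rep(scale, d), 1))
  Tm[seq_len(d), d + 1] <- -scale * centroid
  Tm
}

# Estimate one camera's 3x4 projection from >= 6 non-coplanar
# (3-D point, 2-D observation) correspondences via normalized DLT.
dlt_camera <- function(X, x) {
  n <- nrow(X)
  if (n < 6)
    stop("calibration failure: need at least 6 correspondences, got ", n,
         call. = FALSE)
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6 * max(ev))
    stop("calibration failure: degenerate (near-coplanar) wand geometry",
         call. = FALSE)
  T3 <- conditioning_transform(X)
  T2 <- conditioning_transform(x)
  Xh <- cbind(X, 1) %*% t(T3)
  xh <- cbind(x, 1) %*% t(T2)
  A <- matrix(0, 2 * n, 12)
  A[seq(1, 2 * n, 2), 1:4] <- Xh
  A[seq(1, 2 * n, 2), 9:12] <- -xh[, 1] * Xh
  A[seq(2, 2 * n, 2), 5:8] <- Xh
  A[seq(2, 2 * n, 2), 9:12] <- -xh[, 2] * Xh
  # smallest right singular vector of A via the 12x12 normal matrix
  e <- eigen(crossprod(A), symmetric = TRUE)
  p <- e$vectors[, 12]
  P <- solve(T2) %*% matrix(p, 3, 4, byrow = TRUE) %*% T3
  P / sqrt(sum(P^2))
}

#' Check the wand-sweep frame budget
#'
#' The calibration protocol requires at least 3000 frames per camera; a
#' shorter sweep is allowed but flagged.
#'
#' @param n_frames number of sweep frames captured.
#' @param required required frame count (default 3000).
#' @return A list with `status` (`"pass"` or `"warn"`) and `message`.
#' @export
check_frame_budget <- function(n_frames, required = 3000) {
  stopifnot(n_frames >= 0)
  if (n_frames == 0)
    list(status = "warn", message = "empty sweep: no calibration frames")
  else if (n_frames < required)
    list(status = "warn",
         message = sprintf("only %d calibration frames; %d required",
                           n_frames, required))
  else list(status = "pass",
            message = sprintf("%d calibration frames (>= %d)", n_frames,
                              required))
}

#' Calibrate the rig from a wand sweep
#'
#' Estimates each camera's 3x4 projection matrix by normalized DLT from the
#' known 3-D wand marker positions and the camera's 2-D observations, then
#' computes the calibration systemic error: the RMS over frames of the
#' difference between reconstructed and known wand inter-marker distances.
#' The calibration passes when the systemic error is below `threshold`
#' (default 0.3 mm).
#'
#' @param session a wand-sweep `fm_session` (its truth table supplies the
#'   known wand positions).
#' @param rod the wand phantom used (for its known inter-marker
#'   distances); defaults to the rod recorded in the session manifest.
#' @param threshold systemic-error pass gate in mm.
#' @param sample_max systemic error uses all frames up to this many,
#'   otherwise a seeded random subsample.
#' @param seed seed for the subsample.
#' @return An object of class `fm_calibration`: per-camera projection
#'   matrices `P`, `systemic_error_mm`, `frames_used`, `threshold`, `pass`,
#'   and the frame-budget check.
#' @export
calibrate_dlt <- function(session, rod = NULL, threshold = 0.3,
                          sample_max = 5000, seed = 1) {
  stopifnot(inherits(session, "fm_session"))
  if (is.null(rod)) {
    ref <- session$manifest$rod_reference
    rod <- if (!is.null(ref$spacings_mm)) rod_T(ref$spacings_mm) else rod_T()
  }
  obs <- session$observations
  truth <- session$truth
  tkey <- paste(truth$frame, truth$marker, sep = "\r")
  n_cam <- max(obs$camera)
  P <- vector("list", n_cam)
  n_corr <- integer(n_cam)
  for (ci in seq_len(n_cam)) {
    oc <- obs[obs$camera == ci, , drop = FALSE]
    idx <- match(paste(oc$frame, oc$marker, sep = "\r"), tkey)
    X <- as.matrix(truth[idx, c("x", "y", "z")])
    P[[ci]] <- dlt_camera(X, cbind(oc$u, oc$v))
    n_corr[ci] <- nrow(oc)
  }
  budget <- check_frame_budget(length(unique(truth$frame)))
  err <- calibration_systemic_error(session, P, rod, sample_max, seed)
  structure(list(P = P, systemic_error_mm = err$rms,
                 frames_used = err$frames_used, threshold = threshold,
                 pass = err$rms < threshold, n_correspondences = n_corr,
                 frame_budget = budget,
                 seed = seed, config_hash = session$manifest$config_hash),
            class = "fm_calibration")
}

# RMS over sampled frames of |reconstructed wand pair distance - known|
calibration_systemic_error <- function(session, P, rod, sample_max = 5000,
                                       seed = 1) {
  frames <- unique(session$truth$frame)
  if (length(frames) > sample_max)
    frames <- with_seed(seed, sort(sample(frames, sample_max)))
  known <- rod_pair_distances(rod)
  nm <- nrow(rod$local)
  pairs <- utils::combn(nm, 2)
  recon <- reconstruct_frames(session$observations[
    session$observations$frame %in% frames, , drop = FALSE], P)
  devs <- c()
  for (f in frames) {
    rf <- recon[recon$frame == f, , drop = FALSE]
    pos <- as.matrix(rf[match(paste0("W", seq_len(nm)), rf$marker),
                        c("x", "y", "z")])
    if (anyNA(pos)) next
    d <- apply(pairs, 2, function(ij) dist3(pos[ij[1], ], pos[ij[2], ]))
    devs <- c(devs, d - known)
  }
  if (!length(devs))
    stop("calibration failure: no frame had all wand markers reconstructable",
         call. = FALSE)
  list(rms = sqrt(mean(devs^2)), frames_used = length(frames))
}

#' @export
print.fm_calibration <- function(x, ...) {
  cat(sprintf("DLT calibration of %d cameras\n", length(x$P)))
  cat(sprintf("  systemic error: %.4g mm over %d frames (gate %.2f mm) -> %s\n",
              x$systemic_error_mm, x$frames_used, x$threshold,
              if (x$pass) "PASS" else "FAIL"))
  if (x$frame_budget$status != "pass")
    cat("  warning:", x$frame_budget$message, "\n")
  invisible(x)
}
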