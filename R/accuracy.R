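# Rod-phantom accuracy validation: static and dynamic rod sessions are
# reconstructed, the rod's reference quantity (end-to-end distance
# 176.84 mm, or the 90 degree corner angle) is measured in at least 10
# randomly sampled frames, and the measurements are tested against the
# reference with a one-sample two-sided t-test.

#' Randomly sample analyzable frames
#'
#' Uniform without-replacement seeded sample of frame indices, as used by
#' the accuracy protocol ("at least 10 frames").
#'
#' @param frames vector of analyzable frame indices.
#' @param n sample size (>= 10 by protocol; default 10).
#' @param seed RNG seed.
#' @return Sorted sampled frame indices.
#' @export
sample_frames <- function(frames, n = 10, seed = 1) {
  if (length(frames) < n)
    stop(sprintf("only %d analyzable frames, cannot sample %d",
                 length(frames), n), call. = FALSE)
  with_seed(seed, sort(sample(frames, n)))
}

#' Accuracy statistics against a reference value
#'
#' Mean, sample SD, signed and absolute mean error, and a one-sample
#' two-sided t-test of the measured values against the reference
#' (t = (mean - ref) / (SD / sqrt(n)), df = n - 1).
#'
#' @param values measured values (>= 2).
#' @param reference the manufactured reference value.
#' @param kind label carried in the report (`"distance"` or `"angle"`).
#' @return An object of class `fm_accuracy` with fields `n`, `mean`, `sd`,
#'   `mean_error` (signed), `mean_abs_error`, `t`, `df`, `p` (NA when SD
#'   is 0, with `degenerate = TRUE`).
#' @export
accuracy_stats <- function(values, reference, kind = "distance") {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("need at least 2 measured values", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  s <- sd(values)
  degenerate <- s == 0
  tstat <- if (degenerate && m == reference) 0
           else if (degenerate) NA_real_
           else (m - reference) / (s / sqrt(n))
  p <- if (is.na(tstat)) NA_real_ else 2 * pt(-abs(tstat), df = n - 1)
  structure(list(kind = kind, n = n, values = values, reference = reference,
                 mean = m, sd = s, mean_error = m - reference,
                 mean_abs_error = mean(abs(values - reference)),
                 t = tstat, df = n - 1, p = p, degenerate = degenerate),
            class = "fm_accuracy")
}

#' @export
print.fm_accuracy <- function(x, ...) {
  cat(sprintf("Accuracy report (%s): n = %d sampled frames\n", x$kind, x$n))
  cat(sprintf("  mean %.4f +/- %.4f (reference %.4f)\n", x$mean, x$sd,
              x$reference))
  cat(sprintf("  mean error %.4g, mean absolute error %.4g\n", x$mean_error,
              x$mean_abs_error))
  if (x$degenerate && is.na(x$t))
    cat("  constant values: t-test undefined (SD = 0)\n")
  else
    cat(sprintf("  t = %.3f (df = %d), two-sided p = %.3f\n", x$t, x$df, x$p))
  invisible(x)
}

#' Measure a rod's reference quantity in every reconstructed frame
#'
#' For a linear rod, the end-to-end marker distance; for the L-rod, the
#' vertex angle at the corner marker. Frames with a gap are omitted.
#'
#' @param traj reconstructed rod trajectories (labels `R1`, `R2`, ...).
#' @param rod the `fm_rod` that was captured.
#' @return A data.frame `(frame, value)`.
#' @export
measure_rod_session <- function(traj, rod) {
  frames <- sort(unique(traj$frame))
  nm <- nrow(rod$local)
  vals <- vapply(frames, function(f) {
    d <- traj[traj$frame == f, , drop = FALSE]
    d <- d[match(paste0("R", seq_len(nm)), d$label), , drop = FALSE]
    if (anyNA(d$x) || any(d$gap)) return(NA_real_)
    pos <- as.matrix(d[, c("x", "y", "z")])
    if (rod$kind == "linear") dist3(pos[1, ], pos[2, ])
    else if (rod$kind == "L") angle_at_vertex(pos[2, ], pos[1, ], pos[3, ])
    else stop("unsupported rod kind for accuracy measurement: ", rod$kind,
              call. = FALSE)
  }, numeric(1))
  data.frame(frame = frames, value = vals)[!is.na(vals), , drop = FALSE]
}

#' Run the full rod accuracy protocol
#'
#' Simulates a rod session (static or dynamic), reconstructs it with the
#' supplied calibration, measures the rod's reference quantity in every
#' frame, samples at least 10 frames at random, and reports accuracy
#' statistics with the one-sample t-test against the reference value.
#'
#' @param rig the capture rig.
#' @param calibration an `fm_calibration` for that rig.
#' @param rod [rod_linear()] (distance) or [rod_L()] (angle).
#' @param mode `"static"` or `"dynamic"`.
#' @param duration_s session length in seconds (default: 5 static,
#'   60 dynamic).
#' @param sigma_px observation noise SD (pixels).
#' @param n_sample sampled frame count (>= 10).
#' @param seed top-level seed (split between simulation and sampling).
#' @return An `fm_accuracy` report; the per-frame measurements are in
#'   `$frames`.
#' @export
run_rod_protocol <- function(rig, calibration, rod,
                             mode = c("static", "dynamic"),
                             duration_s = NULL, sigma_px = 0.5,
                             n_sample = 10, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(calibration, "fm_calibration"))
  duration_s <- duration_s %||% if (mode == "static") 5 else 60
  sess <- simulate_rod_session(rig, rod, mode, duration_s, sigma_px,
                               seed = derive_seed(seed, "rod_sim"))
  traj <- reconstruct(sess, calibration)
  per_frame <- measure_rod_session(traj, rod)
  picked <- sample_frames(per_frame$frame, n = n_sample,
                          seed = derive_seed(seed, "rod_sample"))
  vals <- per_frame$value[match(picked, per_frame$frame)]
  reference <- if (rod$kind == "linear") rod$reference$length_mm
               else rod$reference$angle_deg
  rep <- accuracy_stats(vals, reference,
                        kind = if (rod$kind == "linear") "distance"
                               else "angle")
  rep$mode <- mode
  rep$frames <- per_frame
  rep$sampled_frames <- picked
  rep
}
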