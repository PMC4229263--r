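# Facial kinematics: per-landmark velocity/acceleration, per-expression
# motion summaries, and the static distance/angle/direction measure set
# computed on the rest face in anatomical coordinates.

#' Velocity and acceleration of a trajectory
#'
#' Positions are optionally smoothed with a Savitzky-Golay filter (which
#' preserves peak amplitudes better than a moving average), then
#' differentiated by central differences at the capture frequency, with
#' one-sided differences at the endpoints.
#'
#' @param pos n x 3 matrix of positions (mm), uniformly sampled.
#' @param frequency_hz capture frequency (default 100).
#' @param smooth apply Savitzky-Golay smoothing first (default TRUE).
#' @param window,order Savitzky-Golay window length (odd) and polynomial
#'   order; defaults 11 and 3.
#' @return A list with `position` (smoothed), `velocity` (mm/s) and
#'   `acceleration` (mm/s^2), each n x 3.
#' @export
velocity_acceleration <- function(pos, frequency_hz = 100, smooth = TRUE,
                                  window = 11, order = 3) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 5) stop("trajectory too short: need at least 5 frames",
                  call. = FALSE)
  if (anyNA(pos))
    stop("velocity requires gap-free positions (fill gaps first)",
         call. = FALSE)
  if (smooth && n >= window)
    pos <- apply(pos, 2, function(x) signal::sgolayfilt(x, p = order,
                                                        n = window))
  diff_central <- function(x) {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
    d[1] <- x[2] - x[1]
    d[n] <- x[n] - x[n - 1]
    d * frequency_hz
  }
  vel <- apply(pos, 2, diff_central)
  acc <- apply(vel, 2, diff_central)
  list(position = pos, velocity = vel, acceleration = acc)
}

#' Kinematic summary of one expression
#'
#' For each landmark, measures motion relative to its rest position (mean
#' over the rest window): maximum deviation distance, maximum speed,
#' maximum acceleration magnitude, and the moving direction (unit vector
#' of the displacement at maximum deviation, signed per the anatomical
#' conventions: X left+, Y up+, Z forward+).
#'
#' @param traj trajectories in anatomical coordinates.
#' @param expression_frames frame indices of the expression window.
#' @param rest_frames frame indices of the rest window (must precede the
#'   expression window).
#' @param landmarks labels to summarize (default: all in `traj`).
#' @param frequency_hz capture frequency.
#' @param smooth,window,order passed to [velocity_acceleration()].
#' @return A data.frame with one row per landmark: `max_deviation_mm`,
#'   `max_speed_mm_s`, `max_acceleration_mm_s2`, `dir_x`, `dir_y`,
#'   `dir_z`.
#' @export
expression_summary <- function(traj, expression_frames, rest_frames,
                               landmarks = NULL, frequency_hz = NULL,
                               smooth = TRUE, window = 11, order = 3) {
  validate_trajectories(traj)
  if (min(rest_frames) > min(expression_frames))
    stop("the rest window must precede the expression window", call. = FALSE)
  frequency_hz <- frequency_hz %||% attr(traj, "frequency_hz") %||% 100
  landmarks <- landmarks %||% unique(traj$label)
  rest <- rest_pose(traj, rest_frames)
  out <- lapply(landmarks, function(lab) {
    d <- traj[traj$label == lab & traj$frame %in% expression_frames, ,
              drop = FALSE]
    d <- d[order(d$frame), , drop = FALSE]
    d <- d[!d$gap, , drop = FALSE]
    if (!nrow(d))
      stop("expression window contains only gaps for landmark ", lab,
           call. = FALSE)
    pos <- as.matrix(d[, c("x", "y", "z")])
    disp <- sweep(pos, 2, rest[lab, ])
    dev <- sqrt(rowSums(disp^2))
    i_max <- which.max(dev)
    dirv <- if (dev[i_max] > 0) disp[i_max, ] / dev[i_max] else c(0, 0, 0)
    ka <- velocity_acceleration(pos, frequency_hz, smooth, window, order)
    data.frame(landmark = lab,
               max_deviation_mm = dev[i_max],
               max_speed_mm_s = max(sqrt(rowSums(ka$velocity^2))),
               max_acceleration_mm_s2 = max(sqrt(rowSums(ka$acceleration^2))),
               dir_x = dirv[1], dir_y = dirv[2], dir_z = dirv[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# The static measure set: 8 distances, 4 vertex angles and 4 X/Z direction
# pairs between rest landmarks, with the row labels used in reporting.
static_measure_spec <- function() {
  rbind(
    data.frame(parameter = c("G-H (distance)", "g-h (distance)",
                             "I-G (distance)", "I-g (distance)",
                             "H-h(distance)", "E-H(distance)",
                             "E-h(distance)", "II-III (distance)"),
               class = "distance",
               p1 = c("G", "g", "I", "I", "H", "E", "E", "II"),
               p2 = c("H", "h", "G", "g", "h", "H", "h", "III"),
               vertex = NA_character_, stringsAsFactors = FALSE),
    data.frame(parameter = c("∠CED", "∠ced", "∠EHh",
                             "∠ehH"),
               class = "angle",
               p1 = c("C", "c", "E", "e"), p2 = c("D", "d", "h", "H"),
               vertex = c("E", "e", "H", "h"), stringsAsFactors = FALSE),
    data.frame(parameter = c("G-H (direction) X", "G-H (direction) Z",
                             "g-h (direction) X", "g-h (direction) Z",
                             "I-G (direction) X", "I-G (direction) Z",
                             "I-g (direction) X", "I-g (direction) Z"),
               class = "direction",
               p1 = c("G", "G", "g", "g", "I", "I", "I", "I"),
               p2 = c("H", "H", "h", "h", "G", "G", "g", "g"),
               vertex = rep(c("X", "Z"), 4), stringsAsFactors = FALSE))
}

#' Static measures of the rest face
#'
#' Computes the 20-parameter static measure set on rest-pose landmarks in
#' anatomical coordinates: inter-landmark distances (G-H, g-h, I-G, I-g,
#' H-h, E-H, E-h, II-III), vertex angles (the middle letter is the
#' vertex: angle CED, ced, EHh, ehH) and, for the four nasolabial
#' segments, the X and Z components of the unit vector from the first to
#' the second landmark.
#'
#' @param rest named matrix of rest-pose landmark positions in anatomical
#'   coordinates (rownames are landmark codes).
#' @return A data.frame `(parameter, class, value)` with one row per
#'   measure, in the reporting order.
#' @export
static_measures <- function(rest) {
  rest <- as.matrix(rest)
  spec <- static_measure_spec()
  need <- unique(c(spec$p1, spec$p2,
                   spec$vertex[spec$class == "angle"]))
  miss <- setdiff(need, rownames(rest))
  if (length(miss))
    stop("missing landmark(s) for static measures: ",
         paste(miss, collapse = ", "), call. = FALSE)
  value <- numeric(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    p1 <- rest[spec$p1[i], ]; p2 <- rest[spec$p2[i], ]
    value[i] <- switch(spec$class[i],
      distance = dist3(p1, p2),
      angle = angle_at_vertex(p1, rest[spec$vertex[i], ], p2),
      direction = {
        u <- vunit(p2 - p1)
        if (spec$vertex[i] == "X") u[1] else u[3]
      })
  }
  data.frame(parameter = spec$parameter, class = spec$class, value = value,
             stringsAsFactors = FALSE)
}

#' Full static + dynamic analysis of an expression session
#'
#' Convenience wrapper running the head-motion compensation and
#' measurement chain on reconstructed trajectories: fill short gaps, move
#' to helmet coordinates, build the anatomical frame from the rest window,
#' compute static measures and per-expression kinematic summaries.
#'
#' @param traj world-coordinate trajectories from [reconstruct()].
#' @param schedule the session's cue schedule ([default_schedule()]).
#' @param rest_frames frames of the rest window (default: the initial
#'   rest period of the schedule).
#' @param frequency_hz capture frequency.
#' @param nasal_point passed to [anatomical_frame()].
#' @return A list with `static` (static measure table), `dynamic` (one
#'   row per expression x landmark), `frame` (the anatomical frame) and
#'   `trajectories` (anatomical coordinates).
#' @export
analyze_session <- function(traj, schedule, rest_frames = NULL,
                            frequency_hz = NULL, nasal_point = "I") {
  frequency_hz <- frequency_hz %||% attr(traj, "frequency_hz") %||% 100
  rest_frames <- rest_frames %||%
    seq_len(max(1, floor(min(schedule$start_s) * frequency_hz)))
  traj <- fill_gaps(traj)
  helm <- to_helmet(traj)
  rest_h <- rest_pose(helm, rest_frames)
  fr <- anatomical_frame(rest_h, nasal_point = nasal_point)
  anat <- to_anatomical(helm, fr)
  rest_a <- rest_pose(anat, rest_frames)
  static <- static_measures(rest_a)
  dynamic <- lapply(seq_len(nrow(schedule)), function(si) {
    span <- schedule$onset_s[si] + schedule$hold_s[si] + schedule$offset_s[si]
    f0 <- floor(schedule$start_s[si] * frequency_hz) + 1
    f1 <- min(max(anat$frame), ceiling((schedule$start_s[si] + span) *
                                         frequency_hz) + 1)
    s <- expression_summary(anat, expression_frames = f0:f1,
                            rest_frames = rest_frames,
                            frequency_hz = frequency_hz)
    cbind(expression = schedule$index[si], s)
  })
  list(static = static, dynamic = do.call(rbind, dynamic), frame = fr,
       trajectories = anat)
}
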