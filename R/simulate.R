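# Synthetic capture sessions: the simulator stands in for the physical
# system (cameras, wand, rods, a face wearing the helmet). It produces
# per-camera 2-D marker observations plus the ground-truth 3-D positions,
# so that every downstream stage can be validated against truth.
#
# All randomness is driven by an explicit seed; identical configuration and
# seed give identical datasets.

# uniform random rotation via a normalized quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

rotation_xyz <- function(rx, ry, rz) {  # radians, applied as Rz Ry Rx
  cx <- cos(rx); sx <- sin(rx); cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# project without raising on hidden points: invisible when depth <= 0 or
# outside the image
project_quiet <- function(camera, points) {
  pc <- t(camera$R %*% (t(points) - camera$center))
  z <- pc[, 3]
  u <- camera$focal_px * pc[, 1] / z + camera$principal[1]
  v <- camera$focal_px * pc[, 2] / z + camera$principal[2]
  visible <- z > 0 & u >= 0 & u <= camera$image_size[1] &
             v >= 0 & v <= camera$image_size[2]
  list(u = u, v = v, visible = visible)
}

# Build the observation table for a stack of world positions.
# world: data.frame(frame, marker, x, y, z). Noise and dropout are applied
# with the caller's RNG state.
observe_world <- function(rig, world, sigma_px = 0, dropout = 0) {
  pts <- as.matrix(world[, c("x", "y", "z")])
  obs <- vector("list", length(rig$cameras))
  for (ci in seq_along(rig$cameras)) {
    pr <- project_quiet(rig$cameras[[ci]], pts)
    keep <- which(pr$visible)
    if (dropout > 0 && length(keep))
      keep <- keep[runif(length(keep)) >= dropout]
    u <- pr$u[keep]
    v <- pr$v[keep]
    if (sigma_px > 0 && length(keep)) {
      u <- u + rnorm(length(keep), sd = sigma_px)
      v <- v + rnorm(length(keep), sd = sigma_px)
    }
    obs[[ci]] <- data.frame(frame = world$frame[keep], camera = ci,
                            marker = world$marker[keep], u = u, v = v,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, obs)
  out <- out[order(out$frame, out$camera, out$marker), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_session <- function(kind, observations, truth, manifest,
                        frequency_hz = 100) {
  manifest$kind <- kind
  manifest$frequency_hz <- frequency_hz
  manifest$config_hash <- config_hash(manifest[setdiff(names(manifest),
                                                       "config_hash")])
  structure(list(observations = observations, truth = truth,
                 manifest = manifest, clock = capture_clock(frequency_hz)),
            class = "fm_session")
}

#' @export
print.fm_session <- function(x, ...) {
  cat(sprintf("Capture session (%s): %d frames, %d markers, %d observations\n",
              x$manifest$kind, length(unique(x$truth$frame)),
              length(unique(x$truth$marker)), nrow(x$observations)))
  invisible(x)
}

#' Per-frame camera coverage of a session
#'
#' Counts, for every frame and marker, the cameras that observed it, and
#' flags markers seen by fewer than `min_cameras` (the capture protocol
#' requires every reflective point to be detected by at least three
#' cameras; fewer is a quality flag, not a failure).
#'
#' @param session an `fm_session`.
#' @param min_cameras coverage threshold (default 3).
#' @return A data.frame `(frame, marker, n_cameras, flagged)` with an
#'   attribute `ok` (TRUE when nothing is flagged).
#' @export
visibility_report <- function(session, min_cameras = 3) {
  stopifnot(inherits(session, "fm_session"))
  key <- paste(session$truth$frame, session$truth$marker, sep = "\r")
  okey <- paste(session$observations$frame, session$observations$marker,
                sep = "\r")
  n <- as.vector(table(factor(okey, levels = unique(key)))[match(key, unique(key))])
  n[is.na(n)] <- 0L
  out <- data.frame(frame = session$truth$frame,
                    marker = session$truth$marker,
                    n_cameras = n, flagged = n < min_cameras,
                    stringsAsFactors = FALSE)
  attr(out, "ok") <- !any(out$flagged)
  out
}

#' Simulate a calibration-wand sweep
#'
#' Moves the T-rod (three collinear markers at known spacings) through the
#' working volume in randomized rigid poses, recording each camera's 2-D
#' observations together with the true 3-D marker positions. The
#' calibration protocol requires at least 3000 frames per camera.
#'
#' @param rig an [default_rig()] or compatible `fm_rig`.
#' @param rod the wand, normally [rod_T()].
#' @param n_frames number of sweep frames (>= 1).
#' @param sigma_px Gaussian pixel noise SD (default 0.5 px).
#' @param seed RNG seed; identical seed gives an identical dataset.
#' @param volume_mm half-extent of the swept volume around the rig center.
#' @param dropout fraction of observations randomly dropped (stands in for
#'   marker loss during rapid wand motion).
#' @return An `fm_session`.
#' @export
simulate_wand_sweep <- function(rig, rod = rod_T(), n_frames = 3000,
                                sigma_px = 0.5, seed = 1, volume_mm = 120,
                                dropout = 0) {
  stopifnot(inherits(rig, "fm_rig"), inherits(rod, "fm_rod"), n_frames >= 1)
  with_seed(seed, {
    nm <- nrow(rod$local)
    frames <- rep(seq_len(n_frames), each = nm)
    world <- matrix(NA_real_, n_frames * nm, 3)
    for (f in seq_len(n_frames)) {
      R <- random_rotation()
      centre <- runif(3, -volume_mm, volume_mm)
      world[((f - 1) * nm + 1):(f * nm), ] <-
        t(R %*% t(rod$local)) + rep(centre, each = nm)
    }
    truth <- data.frame(frame = frames,
                        marker = rep(paste0("W", seq_len(nm)), n_frames),
                        x = world[, 1], y = world[, 2], z = world[, 3],
                        stringsAsFactors = FALSE)
    obs <- observe_world(rig, truth, sigma_px, dropout)
    new_session("wand_sweep", obs, truth,
                list(seed = seed, sigma_px = sigma_px, n_frames = n_frames,
                     volume_mm = volume_mm, dropout = dropout,
                     rod = rod$kind, rod_reference = rod$reference))
  })
}

# smooth seeded rigid motion: sinusoidal translation + rotation with random
# phases; amplitude chosen to stay inside the shared camera frusta
smooth_pose_fun <- function(trans_amp = c(140, 100, 70),
                            rot_amp_deg = c(25, 25, 25),
                            freq_hz = c(0.23, 0.31, 0.17)) {
  phases <- runif(6, 0, 2 * pi)
  function(t) {
    tr <- trans_amp * sin(2 * pi * freq_hz * t + phases[1:3])
    ang <- rot_amp_deg * pi / 180 * sin(2 * pi * rev(freq_hz) * t + phases[4:6])
    list(R = rotation_xyz(ang[1], ang[2], ang[3]), t = tr)
  }
}

#' Simulate a rod accuracy session
#'
#' Captures a rod phantom either statically (placed still in the volume)
#' or dynamically (moved smoothly through the volume), at 100 frames per
#' second.
#'
#' @param rig an `fm_rig`.
#' @param rod an `fm_rod` (linear or L).
#' @param mode `"static"` or `"dynamic"`.
#' @param duration_s capture duration in seconds (static sessions are
#'   around 5 s, dynamic around 60 s).
#' @param sigma_px Gaussian pixel noise SD.
#' @param seed RNG seed.
#' @return An `fm_session`.
#' @export
simulate_rod_session <- function(rig, rod, mode = c("static", "dynamic"),
                                 duration_s = 5, sigma_px = 0.5, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(rig, "fm_rig"), inherits(rod, "fm_rod"), duration_s > 0)
  freq <- 100
  n_frames <- round(duration_s * freq)
  with_seed(seed, {
    nm <- nrow(rod$local)
    if (mode == "static") {
      R0 <- rotation_xyz(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3),
                         runif(1, -0.3, 0.3))
      t0 <- runif(3, -60, 60)
      pose <- function(t) list(R = R0, t = t0)
    } else {
      pose <- smooth_pose_fun()
    }
    frames <- rep(seq_len(n_frames), each = nm)
    world <- matrix(NA_real_, n_frames * nm, 3)
    for (f in seq_len(n_frames)) {
      p <- pose((f - 1) / freq)
      world[((f - 1) * nm + 1):(f * nm), ] <-
        t(p$R %*% t(rod$local)) + rep(p$t, each = nm)
    }
    truth <- data.frame(frame = frames,
                        marker = rep(paste0("R", seq_len(nm)), n_frames),
                        x = world[, 1], y = world[, 2], z = world[, 3],
                        stringsAsFactors = FALSE)
    obs <- observe_world(rig, truth, sigma_px)
    new_session("rod_session", obs, truth,
                list(seed = seed, sigma_px = sigma_px, mode = mode,
                     duration_s = duration_s, rod = rod$kind,
                     rod_reference = rod$reference))
  })
}

# raised-cosine onset-hold-offset activation in [0, 1]
expression_profile <- function(t, start_s, onset_s = 0.5, hold_s = 1,
                               offset_s = 0.5) {
  u <- t - start_s
  a <- numeric(length(u))
  ramp <- u >= 0 & u < onset_s
  a[ramp] <- (1 - cos(pi * u[ramp] / onset_s)) / 2
  a[u >= onset_s & u < onset_s + hold_s] <- 1
  down <- u >= onset_s + hold_s & u < onset_s + hold_s + offset_s
  a[down] <- (1 + cos(pi * (u[down] - onset_s - hold_s) / offset_s)) / 2
  a
}

#' Default expression schedule
#'
#' A cue schedule running the selected expressions in sequence: an initial
#' rest period, then each expression with a raised-cosine
#' onset (0.5 s) - hold (1 s) - offset (0.5 s) profile, separated by gaps.
#'
#' @param expressions expression indices (subset of 1:10).
#' @param rest_s initial rest duration (s).
#' @param gap_s gap between expressions (s).
#' @param onset_s,hold_s,offset_s temporal profile durations (s).
#' @return A data.frame `(index, start_s, onset_s, hold_s, offset_s)` with
#'   attribute `duration_s` (total session length including trailing rest).
#' @export
default_schedule <- function(expressions = 1:10, rest_s = 1, gap_s = 0.5,
                             onset_s = 0.5, hold_s = 1, offset_s = 0.5) {
  per <- onset_s + hold_s + offset_s + gap_s
  ne <- length(expressions)
  sched <- data.frame(index = expressions,
                      start_s = rest_s + (seq_len(ne) - 1) * per,
                      onset_s = rep(onset_s, ne), hold_s = rep(hold_s, ne),
                      offset_s = rep(offset_s, ne))
  attr(sched, "duration_s") <- rest_s + length(expressions) * per
  sched
}

#' Head-motion specification
#'
#' Smooth sinusoidal rigid head motion with seeded random phases.
#'
#' @param rot_deg amplitude of rotation about X/Y/Z (degrees).
#' @param trans_mm amplitude of translation along X/Y/Z (mm).
#' @param freq_hz motion frequencies (Hz).
#' @return A list consumed by [simulate_expression_session()].
#' @export
head_motion_spec <- function(rot_deg = c(4, 6, 3), trans_mm = c(10, 8, 12),
                             freq_hz = c(0.21, 0.34, 0.13)) {
  list(rot_deg = rot_deg, trans_mm = trans_mm, freq_hz = freq_hz)
}

#' Simulate a facial-expression capture session
#'
#' A face wearing the three-marker helmet performs scheduled expressions
#' while the head moves rigidly. Facial landmarks move with the head rigid
#' motion composed with the expression displacement field; helmet markers
#' follow the head motion only. Ground-truth world and head-frame positions
#' are retained for parameter-recovery testing.
#'
#' @param face an [face_template()].
#' @param rig an `fm_rig`.
#' @param schedule a cue schedule as from [default_schedule()]; its
#'   amplitudes come from the expression registry.
#' @param head_motion a [head_motion_spec()], or NULL for a still head.
#' @param sigma_px Gaussian pixel noise SD.
#' @param seed RNG seed.
#' @param displacements per-landmark peak displacement table, as from
#'   [expression_displacements()].
#' @return An `fm_session` whose `truth_head` element holds the head-frame
#'   positions (rest + expression only, head motion removed).
#' @export
simulate_expression_session <- function(face, rig,
                                        schedule = default_schedule(),
                                        head_motion = head_motion_spec(),
                                        sigma_px = 0.5, seed = 1,
                                        displacements =
                                          expression_displacements()) {
  stopifnot(inherits(face, "fm_face"), inherits(rig, "fm_rig"))
  known <- unique(displacements$index)
  bad <- setdiff(schedule$index, known)
  if (length(bad))
    stop("schedule references unregistered expressions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  freq <- 100
  duration_s <- attr(schedule, "duration_s") %||%
    (max(schedule$start_s + schedule$onset_s + schedule$hold_s +
           schedule$offset_s) + 0.5)
  n_frames <- round(duration_s * freq)
  rest <- face_points(face)
  codes <- rownames(rest)
  nm <- nrow(rest)
  is_face <- face$type == "face"
  with_seed(seed, {
    pose <- if (is.null(head_motion)) {
      function(t) list(R = diag(3), t = c(0, 0, 0))
    } else {
      smooth_pose_fun(trans_amp = head_motion$trans_mm,
                      rot_amp_deg = head_motion$rot_deg,
                      freq_hz = head_motion$freq_hz)
    }
    # per-expression displacement matrices aligned to the template rows
    disp <- lapply(seq_len(nrow(schedule)), function(si) {
      rows <- displacements[displacements$index == schedule$index[si], ]
      D <- matrix(0, nm, 3)
      idx <- match(rows$landmark, codes)
      if (anyNA(idx))
        stop("expression displacement references unknown landmark(s): ",
             paste(rows$landmark[is.na(idx)], collapse = ", "), call. = FALSE)
      D[idx, ] <- as.matrix(rows[, c("dx", "dy", "dz")])
      D
    })
    frames <- rep(seq_len(n_frames), each = nm)
    world <- matrix(NA_real_, n_frames * nm, 3)
    headp <- matrix(NA_real_, n_frames * nm, 3)
    for (f in seq_len(n_frames)) {
      t <- (f - 1) / freq
      ph <- rest
      for (si in seq_len(nrow(schedule))) {
        a <- expression_profile(t, schedule$start_s[si], schedule$onset_s[si],
                                schedule$hold_s[si], schedule$offset_s[si])
        if (a > 0) ph[is_face, ] <- ph[is_face, ] + a * disp[[si]][is_face, ]
      }
      p <- pose(t)
      rows <- ((f - 1) * nm + 1):(f * nm)
      headp[rows, ] <- ph
      world[rows, ] <- t(p$R %*% t(ph)) + rep(p$t, each = nm)
    }
    truth <- data.frame(frame = frames, marker = rep(codes, n_frames),
                        x = world[, 1], y = world[, 2], z = world[, 3],
                        stringsAsFactors = FALSE)
    truth_head <- data.frame(frame = frames, marker = rep(codes, n_frames),
                             x = headp[, 1], y = headp[, 2], z = headp[, 3],
                             stringsAsFactors = FALSE)
    obs <- observe_world(rig, truth, sigma_px)
    sess <- new_session("expression_session", obs, truth,
                        list(seed = seed, sigma_px = sigma_px,
                             schedule = schedule,
                             head_motion = head_motion,
                             duration_s = duration_s))
    sess$truth_head <- truth_head
    sess
  })
}
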