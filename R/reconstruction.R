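# Multi-view triangulation of 2-D marker observations into 3-D
# trajectories, marker labelling/tracking, and short-gap interpolation.

#' Triangulate one marker from multiple camera observations
#'
#' Homogeneous linear least-squares (DLT) triangulation: each observing
#' camera contributes two rows to the design, and the 3-D point is the
#' smallest-eigenvector solution. The residual is the RMS reprojection
#' error across the observing cameras.
#'
#' @param P list of 3x4 camera projection matrices of the observing
#'   cameras.
#' @param uv matrix with one row `(u, v)` per observing camera, in the
#'   same order as `P`.
#' @return A list with `point` (length-3, mm), `residual_px` and
#'   `n_cameras`.
#' @export
triangulate <- function(P, uv) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2)
  n <- length(P)
  if (n < 2)
    stop("untriangulatable: fewer than 2 observing cameras", call. = FALSE)
  stopifnot(nrow(uv) == n)
  A <- matrix(0, 2 * n, 4)
  for (i in seq_len(n)) {
    A[2 * i - 1, ] <- uv[i, 1] * P[[i]][3, ] - P[[i]][1, ]
    A[2 * i, ] <- uv[i, 2] * P[[i]][3, ] - P[[i]][2, ]
  }
  e <- eigen(crossprod(A), symmetric = TRUE)
  Xh <- e$vectors[, 4]
  if (abs(Xh[4]) < 1e-14)
    stop("triangulation failed: point at infinity", call. = FALSE)
  X <- Xh[1:3] / Xh[4]
  resid <- vapply(seq_len(n), function(i) {
    pr <- P[[i]] %*% c(X, 1)
    sum((pr[1:2] / pr[3] - uv[i, ])^2)
  }, numeric(1))
  list(point = X, residual_px = sqrt(mean(resid)), n_cameras = n)
}

# Triangulate every (frame, marker) group of an observation table.
# Returns a data.frame (frame, marker, x, y, z, n_cameras, residual_px);
# groups seen by < 2 cameras are omitted (the caller records the gap).
reconstruct_frames <- function(obs, P) {
  key <- paste(obs$frame, obs$marker, sep = "\r")
  groups <- split(seq_len(nrow(obs)), key)
  out <- vector("list", length(groups))
  k <- 0L
  for (g in groups) {
    if (length(g) < 2) next
    cams <- obs$camera[g]
    tri <- triangulate(P[cams], cbind(obs$u[g], obs$v[g]))
    k <- k + 1L
    out[[k]] <- c(obs$frame[g[1]], tri$point, tri$n_cameras, tri$residual_px)
  }
  if (k == 0L)
    return(data.frame(frame = integer(), marker = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      n_cameras = integer(), residual_px = numeric()))
  mk <- vapply(groups, function(g) obs$marker[g[1]], character(1))
  keep <- vapply(groups, length, integer(1)) >= 2
  m <- do.call(rbind, out[seq_len(k)])
  data.frame(frame = as.integer(m[, 1]), marker = unname(mk[keep]),
             x = m[, 2], y = m[, 3], z = m[, 4],
             n_cameras = as.integer(m[, 5]), residual_px = m[, 6],
             stringsAsFactors = FALSE)
}

#' Reconstruct labeled 3-D trajectories from a session
#'
#' Triangulates every marker in every frame of a capture session using a
#' calibration, keeping the session's marker identities. Markers observed
#' by fewer than 2 cameras in a frame become gaps; markers observed by
#' fewer than `qc_min_cameras` are QC-flagged but kept.
#'
#' @param session an `fm_session`.
#' @param calibration an `fm_calibration` (or a list of 3x4 matrices).
#' @param qc_min_cameras coverage QC threshold (default 3).
#' @return A trajectory data.frame `(frame, time_s, label, x, y, z,
#'   n_cameras, gap, residual_px)` covering every (frame, marker) of the
#'   session truth table.
#' @export
reconstruct <- function(session, calibration, qc_min_cameras = 3) {
  stopifnot(inherits(session, "fm_session"))
  P <- if (inherits(calibration, "fm_calibration")) calibration$P
       else calibration
  rec <- reconstruct_frames(session$observations, P)
  truth <- session$truth
  idx <- match(paste(truth$frame, truth$marker, sep = "\r"),
               paste(rec$frame, rec$marker, sep = "\r"))
  out <- data.frame(frame = truth$frame,
                    time_s = frame_time(session$clock, truth$frame - 1L),
                    label = truth$marker,
                    x = rec$x[idx], y = rec$y[idx], z = rec$z[idx],
                    n_cameras = rec$n_cameras[idx],
                    gap = is.na(idx),
                    residual_px = rec$residual_px[idx],
                    stringsAsFactors = FALSE)
  out$n_cameras[is.na(out$n_cameras)] <- 0L
  out$qc_flag <- out$n_cameras < qc_min_cameras
  attr(out, "frequency_hz") <- session$clock$frequency_hz
  validate_trajectories(out)
  out
}

#' Label and track unlabeled per-frame point clouds
#'
#' Assigns landmark labels to unlabeled reconstructed points. The first
#' frame is labeled by mutual-nearest-neighbour matching against a labeled
#' template layout (each template marker and cloud point must choose each
#' other; a cloud point claimed by two template markers is an error).
#' Subsequent frames are tracked by nearest-neighbour gating from each
#' trajectory's last known position, with maximum inter-frame displacement
#' `v_max / frequency`; unmatched trajectories get a gap.
#'
#' @param clouds list of frame clouds: each a list with `frame` and
#'   `points` (n x 3 matrix), optionally `n_cameras` and `residual_px`.
#' @param template named n x 3 matrix: expected marker layout at the first
#'   frame (rownames are labels).
#' @param v_max gating speed in mm/s (default 500).
#' @param frequency_hz capture frequency (default 100).
#' @return A trajectory data.frame as in [reconstruct()].
#' @export
label_and_track <- function(clouds, template, v_max = 500,
                            frequency_hz = 100) {
  stopifnot(length(clouds) >= 1, !is.null(rownames(template)))
  labels <- rownames(template)
  gate <- v_max / frequency_hz
  first <- clouds[[1]]
  if (nrow(first$points) < nrow(template))
    stop("first frame must contain all template markers", call. = FALSE)
  # mutual nearest neighbour template -> cloud
  D <- outer(seq_len(nrow(template)), seq_len(nrow(first$points)),
             Vectorize(function(i, j) dist3(template[i, ], first$points[j, ])))
  near_t <- apply(D, 1, which.min)
  near_c <- apply(D, 2, which.min)
  if (anyDuplicated(near_t)) {
    dup <- near_t[duplicated(near_t)][1]
    stop("ambiguous initial labeling: template markers ",
         paste(labels[near_t == dup], collapse = ", "),
         " claim the same cloud point", call. = FALSE)
  }
  if (!all(near_c[near_t] == seq_along(near_t)))
    stop("ambiguous initial labeling: template/cloud matches not mutual",
         call. = FALSE)
  last_pos <- first$points[near_t, , drop = FALSE]
  rownames(last_pos) <- labels
  rows <- vector("list", length(clouds))
  emit <- function(cloud, assign_idx) {
    pos <- matrix(NA_real_, length(labels), 3)
    nc <- integer(length(labels)); res <- rep(NA_real_, length(labels))
    ok <- !is.na(assign_idx)
    pos[ok, ] <- cloud$points[assign_idx[ok], , drop = FALSE]
    if (!is.null(cloud$n_cameras)) nc[ok] <- cloud$n_cameras[assign_idx[ok]]
    if (!is.null(cloud$residual_px)) res[ok] <- cloud$residual_px[assign_idx[ok]]
    data.frame(frame = cloud$frame,
               time_s = (cloud$frame - 1) / frequency_hz, label = labels,
               x = pos[, 1], y = pos[, 2], z = pos[, 3], n_cameras = nc,
               gap = !ok, residual_px = res, stringsAsFactors = FALSE)
  }
  rows[[1]] <- emit(first, near_t)
  for (ci in seq_along(clouds)[-1]) {
    cloud <- clouds[[ci]]
    np <- nrow(cloud$points)
    assign_idx <- rep(NA_integer_, length(labels))
    if (np > 0) {
      D <- outer(seq_along(labels), seq_len(np), Vectorize(function(i, j) {
        if (anyNA(last_pos[i, ])) Inf else dist3(last_pos[i, ], cloud$points[j, ])
      }))
      # greedy one-to-one by increasing distance within the gate
      repeat {
        m <- which.min(D)
        if (!length(m) || !is.finite(D[m]) || D[m] > gate) break
        i <- (m - 1) %% length(labels) + 1
        j <- (m - 1) %/% length(labels) + 1
        assign_idx[i] <- j
        D[i, ] <- Inf; D[, j] <- Inf
      }
    }
    ok <- !is.na(assign_idx)
    last_pos[ok, ] <- cloud$points[assign_idx[ok], , drop = FALSE]
    rows[[ci]] <- emit(cloud, assign_idx)
  }
  out <- do.call(rbind, rows)
  out$qc_flag <- out$n_cameras < 3
  attr(out, "frequency_hz") <- frequency_hz
  validate_trajectories(out)
  out
}

#' Interpolate short trajectory gaps
#'
#' Fills interior gaps of at most `max_gap_frames` frames by cubic
#' (spline) interpolation of each coordinate; longer gaps and gaps at the
#' sequence edges are left flagged (no extrapolation).
#'
#' @param traj a trajectory data.frame.
#' @param max_gap_frames longest gap run to fill (default 10 frames,
#'   0.1 s at 100 Hz).
#' @return The trajectory with filled positions; filled rows have
#'   `gap = FALSE` and `interpolated = TRUE`.
#' @export
fill_gaps <- function(traj, max_gap_frames = 10) {
  validate_trajectories(traj)
  traj$interpolated <- FALSE
  for (lab in unique(traj$label)) {
    sel <- which(traj$label == lab)
    sel <- sel[order(traj$frame[sel])]
    g <- traj$gap[sel]
    if (!any(g) || all(g)) next
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    known <- sel[!g]
    for (k in which(r$values)) {
      if (starts[k] == 1 || ends[k] == length(sel)) next  # edge: refuse
      if (r$lengths[k] > max_gap_frames) next
      fill <- sel[starts[k]:ends[k]]
      for (coord in c("x", "y", "z")) {
        traj[[coord]][fill] <- spline(x = traj$frame[known],
                                      y = traj[[coord]][known],
                                      xout = traj$frame[fill],
                                      method = "fmm")$y
      }
      traj$gap[fill] <- FALSE
      traj$interpolated[fill] <- TRUE
    }
  }
  traj
}
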