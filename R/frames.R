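# Head-fixed reference frames. The three rigid helmet markers define a
# per-frame "absolute" coordinate system that removes head motion; the
# anatomical frame (horizontal / sagittal / coronal planes built from the
# tragus points and the nasal reference landmark at rest) carries the sign
# conventions used for all reported directions: X left(+), Y up(+),
# Z forward(+, toward the cameras).

#' Build the helmet coordinate frame from its three markers
#'
#' The three helmet markers determine an origin (their centroid) and a
#' plane; the frame's third axis is the unit line perpendicular to that
#' plane through the origin. The first axis points from the origin toward
#' marker 1 (orthogonalized against the normal) and the second completes a
#' right-handed triad.
#'
#' @param m1,m2,m3 helmet marker positions (world, mm).
#' @param normal_hint optional vector: the normal's sign is chosen to have
#'   a positive dot product with it (used to fix the sign toward the face
#'   at session start, then tracked for continuity).
#' @return An object of class `fm_frame`: `origin` and `axes` (3x3, axes
#'   as columns, orthonormal, right-handed).
#' @export
helmet_frame <- function(m1, m2, m3, normal_hint = NULL) {
  m1 <- as_vec3(m1, "m1"); m2 <- as_vec3(m2, "m2"); m3 <- as_vec3(m3, "m3")
  n <- vcross(m2 - m1, m3 - m1)
  if (vnorm(n) / 2 < 1e-6)
    stop("degenerate helmet frame: markers are (near-)collinear",
         call. = FALSE)
  n <- vunit(n)
  if (!is.null(normal_hint) && sum(n * normal_hint) < 0) n <- -n
  origin <- (m1 + m2 + m3) / 3
  a1 <- m1 - origin
  a1 <- vunit(a1 - sum(a1 * n) * n)
  a2 <- vcross(n, a1)
  axes <- cbind(a1, a2, n)
  dimnames(axes) <- NULL
  structure(list(origin = origin, axes = axes), class = "fm_frame")
}

new_frame <- function(origin, axes) {
  structure(list(origin = origin, axes = axes), class = "fm_frame")
}

#' @export
print.fm_frame <- function(x, ...) {
  cat("Coordinate frame, origin (",
      paste(signif(x$origin, 6), collapse = ", "), ")\n", sep = "")
  print(signif(x$axes, 6))
  invisible(x)
}

# express world points (n x 3) in a frame
to_frame_coords <- function(frame, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1, 3)
  t(crossprod(frame$axes, t(pts) - frame$origin))
}

#' Re-express trajectories in helmet coordinates
#'
#' For every frame, builds the helmet frame from the three helmet-marker
#' positions and re-expresses all other landmark positions in it, removing
#' rigid head motion. The helmet-plane normal sign is fixed toward the
#' face centroid on the first analyzable frame and tracked for continuity
#' afterwards. Frames where a helmet marker is missing are excluded
#' (dropped with a message).
#'
#' @param traj a trajectory data.frame in world coordinates.
#' @param helmet_labels the three helmet marker labels.
#' @return The face-landmark trajectories in helmet coordinates (helmet
#'   markers removed), same columns as the input.
#' @export
to_helmet <- function(traj, helmet_labels = c("HM1", "HM2", "HM3")) {
  validate_trajectories(traj)
  if (!all(helmet_labels %in% traj$label))
    stop("helmet markers not found in trajectories: ",
         paste(setdiff(helmet_labels, traj$label), collapse = ", "),
         call. = FALSE)
  frames <- sort(unique(traj$frame))
  is_h <- traj$label %in% helmet_labels
  hm <- traj[is_h, , drop = FALSE]
  face <- traj[!is_h, , drop = FALSE]
  out <- face
  prev_normal <- NULL
  dropped <- 0L
  keep <- rep(TRUE, nrow(face))
  for (f in frames) {
    hrows <- hm[hm$frame == f, , drop = FALSE]
    hrows <- hrows[match(helmet_labels, hrows$label), , drop = FALSE]
    frows <- which(face$frame == f)
    if (anyNA(hrows$x) || any(hrows$gap)) {
      keep[frows] <- FALSE
      dropped <- dropped + 1L
      next
    }
    m <- as.matrix(hrows[, c("x", "y", "z")])
    hint <- prev_normal
    if (is.null(hint)) {
      fc <- colMeans(as.matrix(face[frows, c("x", "y", "z")]), na.rm = TRUE)
      hint <- fc - colMeans(m)
    }
    fr <- helmet_frame(m[1, ], m[2, ], m[3, ], normal_hint = hint)
    prev_normal <- fr$axes[, 3]
    pts <- as.matrix(face[frows, c("x", "y", "z")])
    loc <- to_frame_coords(fr, pts)
    out$x[frows] <- loc[, 1]; out$y[frows] <- loc[, 2]; out$z[frows] <- loc[, 3]
  }
  if (dropped > 0)
    message(dropped, " frame(s) excluded: helmet marker gap")
  out <- out[keep, , drop = FALSE]
  attr(out, "frequency_hz") <- attr(traj, "frequency_hz")
  attr(out, "coordinates") <- "helmet"
  out
}

#' Build the anatomical reference frame from rest-pose landmarks
#'
#' Constructs the three anatomical planes from the rest face: the
#' horizontal plane through the two tragus points (A, a) and the nasal
#' reference point; the sagittal plane perpendicular to it through the
#' nasal point; and the coronal plane through the left tragus,
#' perpendicular to both. Axes follow the reporting conventions: X is the
#' sagittal-plane normal (left "+"), Y the horizontal-plane normal
#' (up "+"), Z = X x Y (forward "+", toward the cameras). The origin is
#' the intersection of the three planes (the left tragus projected onto
#' the sagittal plane along X).
#'
#' @param rest named n x 3 matrix (or data.frame with rownames) of
#'   rest-pose landmark positions, normally in helmet coordinates.
#' @param nasal_point landmark anchoring the horizontal and sagittal
#'   planes; default `"I"` (root of the columella nasi), configurable to
#'   `"K"`.
#' @return An `fm_frame` with attributes recording the construction
#'   landmarks.
#' @export
anatomical_frame <- function(rest, nasal_point = "I") {
  rest <- as.matrix(rest)
  need <- c("A", "a", nasal_point)
  miss <- setdiff(need, rownames(rest))
  if (length(miss))
    stop("missing landmark(s) for anatomical frame: ",
         paste(miss, collapse = ", "), call. = FALSE)
  A <- rest["A", ]; a <- rest["a", ]; I <- rest[nasal_point, ]
  horiz <- plane_from_points(A, a, I)
  Y <- horiz$normal
  # up: from the lower lip toward the brow center (fallback: eyelid pair)
  up_ref <- if (all(c("J", "III") %in% rownames(rest))) {
    rest["J", ] - rest["III", ]
  } else if (all(c("B", "b", "H", "h") %in% rownames(rest))) {
    (rest["B", ] + rest["b", ]) / 2 - (rest["H", ] + rest["h", ]) / 2
  } else stop("cannot orient the vertical axis: need J/III or B,b/H,h",
              call. = FALSE)
  if (sum(Y * up_ref) < 0) Y <- -Y
  X <- A - a                      # right tragus -> left tragus: left is "+"
  X <- vunit(X - sum(X * Y) * Y)  # in the horizontal plane
  Z <- vcross(X, Y)               # forward "+" (toward the cameras)
  origin <- A + X * sum(X * (I - A))
  axes <- cbind(X, Y, Z)
  dimnames(axes) <- NULL
  fr <- new_frame(unname(origin), axes)
  attr(fr, "nasal_point") <- nasal_point
  attr(fr, "construction") <- list(A = A, a = a, nasal = I)
  fr
}

#' Re-express trajectories in the anatomical frame
#'
#' Applies a fixed anatomical frame (computed once at rest, normally in
#' helmet coordinates) to helmet-coordinate trajectories.
#'
#' @param traj trajectories in helmet coordinates.
#' @param frame an [anatomical_frame()].
#' @return Trajectories in anatomical coordinates.
#' @export
to_anatomical <- function(traj, frame) {
  validate_trajectories(traj)
  stopifnot(inherits(frame, "fm_frame"))
  ok <- !traj$gap
  loc <- to_frame_coords(frame, as.matrix(traj[ok, c("x", "y", "z")]))
  traj$x[ok] <- loc[, 1]; traj$y[ok] <- loc[, 2]; traj$z[ok] <- loc[, 3]
  attr(traj, "coordinates") <- "anatomical"
  traj
}

#' Rest-pose landmark positions from a trajectory window
#'
#' Mean position of every label over a frame window (ignoring gaps).
#'
#' @param traj a trajectory data.frame.
#' @param frames frame indices of the rest window.
#' @return A named n x 3 matrix.
#' @export
rest_pose <- function(traj, frames) {
  d <- traj[traj$frame %in% frames & !traj$gap, , drop = FALSE]
  if (!nrow(d)) stop("rest window contains only gaps", call. = FALSE)
  labs <- unique(d$label)
  m <- t(vapply(labs, function(l) {
    colMeans(as.matrix(d[d$label == l, c("x", "y", "z")]))
  }, numeric(3)))
  rownames(m) <- labs
  m
}
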