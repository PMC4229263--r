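# Pinhole camera models and the six-camera capture rig.
#
# Cameras are idealized pinholes (no lens distortion): world point X (mm)
# maps to pixel (u, v) via x_cam = R (X - C), u = f x/z + cx, v = f y/z + cy.
# The rig arranges six cameras in a symmetric "L" facing the capture volume.

#' Construct a pinhole camera
#'
#' @param center camera center in world coordinates (mm).
#' @param look_at point the optical axis passes through (default origin).
#' @param up approximate up direction used to fix the camera roll.
#' @param focal_px focal length in pixels.
#' @param image_size c(width, height) in pixels.
#' @param principal principal point (pixels); defaults to the image center.
#' @return An object of class `fm_camera`.
#' @export
camera_model <- function(center, look_at = c(0, 0, 0), up = c(0, 1, 0),
                         focal_px = 2000, image_size = c(1360, 1024),
                         principal = image_size / 2) {
  center <- as_vec3(center, "center")
  if (focal_px <= 0) stop("focal length must be positive", call. = FALSE)
  zc <- vunit(as_vec3(look_at, "look_at") - center)
  up <- as_vec3(up, "up")
  if (vnorm(vcross(up, zc)) < 1e-9) up <- c(0, 0, 1)  # axis parallel to up
  xc <- vunit(vcross(up, zc))
  yc <- vcross(zc, xc)
  R <- rbind(xc, yc, zc)
  dimnames(R) <- NULL
  structure(list(R = R, center = center, focal_px = focal_px,
                 principal = as.numeric(principal),
                 image_size = as.numeric(image_size)),
            class = "fm_camera")
}

#' 3x4 projection matrix of a camera
#'
#' @param camera an [camera_model()].
#' @return The matrix `K [R | -R C]`.
#' @export
camera_matrix <- function(camera) {
  stopifnot(inherits(camera, "fm_camera"))
  K <- matrix(c(camera$focal_px, 0, camera$principal[1],
                0, camera$focal_px, camera$principal[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  K %*% cbind(camera$R, -camera$R %*% camera$center)
}

#' Project world points into a camera
#'
#' @param camera an [camera_model()].
#' @param points a numeric length-3 vector or an n x 3 matrix (mm).
#' @return A data.frame with columns `u`, `v`, `depth_mm`, `visible`
#'   (inside the image bounds). Points at non-positive depth raise an error.
#' @export
project <- function(camera, points) {
  stopifnot(inherits(camera, "fm_camera"))
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  pc <- t(camera$R %*% (t(points) - camera$center))
  z <- pc[, 3]
  if (any(z <= 0))
    stop("point behind camera (non-positive depth)", call. = FALSE)
  u <- camera$focal_px * pc[, 1] / z + camera$principal[1]
  v <- camera$focal_px * pc[, 2] / z + camera$principal[2]
  visible <- u >= 0 & u <= camera$image_size[1] &
             v >= 0 & v <= camera$image_size[2]
  data.frame(u = u, v = v, depth_mm = z, visible = visible)
}

#' Default six-camera rig in a symmetric "L" layout
#'
#' Six pinhole cameras placed at the working distance from the volume
#' center, arranged as two perpendicular rows of three (a horizontal arm
#' and a vertical arm), all aimed at the volume center. The subject faces
#' +Z toward the rig.
#'
#' @param working_distance_mm distance from each camera to the volume
#'   center (default 800 mm).
#' @param focal_px,image_size passed to [camera_model()].
#' @return An object of class `fm_rig`: a list of `fm_camera`s plus layout
#'   metadata.
#' @export
default_rig <- function(working_distance_mm = 800, focal_px = 2000,
                        image_size = c(1360, 1024)) {
  offsets <- rbind(                 # (x, y) arm offsets of the "L", mm
    c(-420, -240), c(0, -240), c(420, -240),   # horizontal arm
    c(420, 120), c(420, 480), c(420, 840))     # vertical arm
  cams <- lapply(seq_len(nrow(offsets)), function(i) {
    dirv <- vunit(c(offsets[i, 1], offsets[i, 2], working_distance_mm))
    camera_model(center = dirv * working_distance_mm,
                 focal_px = focal_px, image_size = image_size)
  })
  structure(list(cameras = cams, working_distance_mm = working_distance_mm,
                 layout = "symmetric-L"), class = "fm_rig")
}

#' @export
print.fm_rig <- function(x, ...) {
  cat(sprintf("Capture rig: %d cameras (%s), working distance %g mm\n",
              length(x$cameras), x$layout, x$working_distance_mm))
  invisible(x)
}

# true projection matrices of a rig, as a list
rig_matrices <- function(rig) lapply(rig$cameras, camera_matrix)
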