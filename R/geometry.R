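# Elementary 3-D geometry on marker positions. All coordinates are in
# millimetres; all angles are reported in degrees.

as_vec3 <- function(p, arg = deparse(substitute(p))) {
  p <- as.numeric(p)
  if (length(p) != 3L)
    stop(sprintf("'%s' must have exactly 3 components", arg), call. = FALSE)
  if (!all(is.finite(p)))
    stop(sprintf("'%s' has non-finite components (corrupted trajectory?)", arg),
         call. = FALSE)
  p
}

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Euclidean distance between two 3-D marker positions
#'
#' @param p,q numeric length-3 vectors (millimetres).
#' @return Distance in millimetres.
#' @examples
#' dist3(c(0, 0, 0), c(176.84, 0, 0))
#' @export
dist3 <- function(p, q) {
  p <- as_vec3(p, "p"); q <- as_vec3(q, "q")
  vnorm(p - q)
}

#' Angle at a vertex formed by three 3-D points
#'
#' Computes the angle `a`-`v`-`b` at the vertex `v`, i.e. the angle between
#' the rays from `v` to `a` and from `v` to `b`.
#'
#' @param a,v,b numeric length-3 vectors (millimetres); `v` is the vertex.
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' angle_at_vertex(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
angle_at_vertex <- function(a, v, b) {
  a <- as_vec3(a, "a"); v <- as_vec3(v, "v"); b <- as_vec3(b, "b")
  u1 <- a - v; u2 <- b - v
  if (vnorm(u1) == 0 || vnorm(u2) == 0)
    stop("degenerate angle: a ray endpoint coincides with the vertex",
         call. = FALSE)
  cosang <- sum(vunit(u1) * vunit(u2))
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Plane through three non-collinear points
#'
#' @param p1,p2,p3 numeric length-3 vectors (millimetres).
#' @param tol collinearity tolerance: triangle area below `tol` mm^2 is an
#'   error.
#' @return An object of class `fm_plane`: a list with `point` (a point on the
#'   plane) and `normal` (unit normal).
#' @export
plane_from_points <- function(p1, p2, p3, tol = 1e-6) {
  p1 <- as_vec3(p1, "p1"); p2 <- as_vec3(p2, "p2"); p3 <- as_vec3(p3, "p3")
  n <- vcross(p2 - p1, p3 - p1)
  area <- vnorm(n) / 2
  if (area < tol)
    stop("degenerate plane: the three points are (near-)collinear",
         call. = FALSE)
  structure(list(point = p1, normal = vunit(n)), class = "fm_plane")
}

#' Signed distance from a point to a plane
#'
#' @param plane an [plane_from_points()] result.
#' @param p numeric length-3 vector.
#' @return Signed distance in millimetres (positive on the normal side).
#' @export
point_plane_distance <- function(plane, p) {
  stopifnot(inherits(plane, "fm_plane"))
  sum((as_vec3(p, "p") - plane$point) * plane$normal)
}

#' @export
print.fm_plane <- function(x, ...) {
  cat("Plane through (", paste(signif(x$point, 6), collapse = ", "),
      ") with unit normal (", paste(signif(x$normal, 6), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
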