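# Calibration and accuracy phantoms, and the parametric face template.

#' Rod phantoms
#'
#' Rigid marker phantoms used for calibration and accuracy validation:
#'
#' * `rod_linear()` — two markers at a manufactured separation of
#'   176.84 mm; its end-to-end distance is the accuracy reference.
#' * `rod_L()` — three markers forming a right angle at the corner marker
#'   (the first marker); the 90 degree corner is the angular reference.
#' * `rod_T()` — the calibration wand: three collinear markers at known
#'   spacings, swept through the volume during calibration.
#'
#' @param length_mm end-to-end length of the linear rod (mm).
#' @param arm_mm arm length of the L-rod (mm).
#' @param spacings_mm the two segment lengths of the T-rod's collinear
#'   markers (mm).
#' @return An object of class `fm_rod`: list with `kind`, `local` (markers
#'   as rows, phantom-local mm) and `reference` (the known quantity).
#' @name rods
NULL

new_rod <- function(kind, local, reference) {
  local <- sweep(local, 2, colMeans(local))  # body frame at the centroid
  structure(list(kind = kind, local = local, reference = reference),
            class = "fm_rod")
}

#' @rdname rods
#' @export
rod_linear <- function(length_mm = 176.84) {
  new_rod("linear", rbind(c(0, 0, 0), c(length_mm, 0, 0)),
          list(length_mm = length_mm))
}

#' @rdname rods
#' @export
rod_L <- function(arm_mm = 120) {
  new_rod("L", rbind(c(0, 0, 0), c(arm_mm, 0, 0), c(0, arm_mm, 0)),
          list(angle_deg = 90, arm_mm = arm_mm))
}

#' @rdname rods
#' @export
rod_T <- function(spacings_mm = c(100, 150)) {
  s <- as.numeric(spacings_mm)
  stopifnot(length(s) == 2, all(s > 0))
  local <- rbind(c(0, 0, 0), c(s[1], 0, 0), c(s[1] + s[2], 0, 0))
  new_rod("T", local, list(spacings_mm = s))
}

#' @export
print.fm_rod <- function(x, ...) {
  cat(sprintf("%s-rod phantom with %d markers\n", x$kind, nrow(x$local)))
  invisible(x)
}

# pairwise inter-marker distances of a rod, named "d<i>_<j>"
rod_pair_distances <- function(rod) {
  n <- nrow(rod$local)
  pairs <- utils::combn(n, 2)
  d <- apply(pairs, 2, function(ij) dist3(rod$local[ij[1], ], rod$local[ij[2], ]))
  names(d) <- apply(pairs, 2, function(ij) paste0("d", ij[1], "_", ij[2]))
  d
}

#' Rest-pose face template with helmet markers
#'
#' Loads the synthetic rest-pose template: 21 facial landmarks plus 3 rigid
#' helmet markers, in head-fixed coordinates (X left+, Y up+, Z forward+,
#' origin between the tragus points). Left/right homologue pairs are
#' mirror-symmetric in X; the helmet markers are rigid with the head.
#'
#' @param file optional path to an override template with columns
#'   `code, type, x, y, z`.
#' @return An object of class `fm_face`: data.frame with columns `code`,
#'   `type` (`face`/`helmet`), `x`, `y`, `z`.
#' @export
face_template <- function(file = NULL) {
  d <- read.csv(file %||% extdata_path("face_template_synthetic.csv"),
                comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("code", "type", "x", "y", "z") %in% names(d)))
  reg <- landmark_registry()
  miss <- setdiff(reg$code, d$code[d$type == "face"])
  if (length(miss))
    stop("face template is missing landmarks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (sum(d$type == "helmet") != 3L)
    stop("face template must carry exactly 3 helmet markers", call. = FALSE)
  class(d) <- c("fm_face", class(d))
  d
}

face_points <- function(face) {
  m <- as.matrix(face[, c("x", "y", "z")])
  rownames(m) <- face$code
  m
}
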