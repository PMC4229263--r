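# Landmark and expression registries, capture clock, trajectories.
#
# The landmark registry holds the 21 facial observational points. Codes are
# case-sensitive: uppercase/lowercase letter pairs are left/right homologues
# (A = left tragus, a = right tragus, ...); I, J, K, II, III are midline.

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "facemotion3d")
  if (p == "") stop("packaged data file not found: ", file, call. = FALSE)
  p
}

#' The 21-landmark facial registry
#'
#' Returns the registry of the 21 observational points used for facial
#' kinematics: bilateral pairs (uppercase = left, lowercase = right) for
#' tragus (A/a), brow (B/b), upper and lower eyelid (C/c, D/d), lateral and
#' medial eye corner (E/e, F/f), nasal ala (G/g) and mouth corner (H/h),
#' plus the midline points I (root of the columella nasi), J (center of the
#' eyebrows), K (nasal dorsum), II (philtrum) and III (lower lip).
#'
#' @param file optional path to a user override table with columns
#'   `code, description, side`.
#' @return A data.frame with columns `code`, `description`,
#'   `side` (`left`/`right`/`midline`).
#' @export
landmark_registry <- function(file = NULL) {
  reg <- read.csv(file %||% extdata_path("landmarks.csv"),
                  comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("code", "description", "side") %in% names(reg)))
  if (anyDuplicated(reg$code))
    stop("duplicate landmark codes in registry", call. = FALSE)
  if (!all(reg$side %in% c("left", "right", "midline")))
    stop("landmark side must be left, right or midline", call. = FALSE)
  reg
}

#' The 10 standardized facial expressions
#'
#' One registry row per expression, carrying its active-landmark set and
#' nominal amplitude (the largest per-landmark peak displacement, mm). The
#' amplitudes are synthetic simulator choices, not measured values.
#'
#' @param file optional path to an override table with columns
#'   `index, name, landmark, dx, dy, dz` (one row per active landmark).
#' @return A data.frame with columns `index`, `name`, `landmarks`
#'   (comma-separated active set) and `amplitude_mm`.
#' @seealso [expression_displacements()] for the per-landmark vectors.
#' @export
expression_registry <- function(file = NULL) {
  d <- expression_displacements(file)
  amp <- sqrt(d$dx^2 + d$dy^2 + d$dz^2)
  out <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$index), function(i) {
    data.frame(index = d$index[i[1]], name = d$name[i[1]],
               landmarks = paste(d$landmark[i], collapse = ","),
               amplitude_mm = max(amp[i]), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-landmark peak displacement vectors for each expression
#'
#' @inheritParams expression_registry
#' @return A data.frame with columns `index`, `name`, `landmark`,
#'   `dx`, `dy`, `dz` (peak displacement, mm, head-fixed frame).
#' @export
expression_displacements <- function(file = NULL) {
  d <- read.csv(file %||% extdata_path("expressions_synthetic.csv"),
                comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("index", "name", "landmark", "dx", "dy", "dz") %in% names(d)))
  d
}

#' Capture clock
#'
#' Maps frame indices to time for a fixed-frequency capture.
#'
#' @param frequency_hz capture frequency in frames per second (default 100).
#' @return An object of class `fm_clock`.
#' @export
capture_clock <- function(frequency_hz = 100) {
  if (!is.finite(frequency_hz) || frequency_hz <= 0)
    stop("capture frequency must be positive", call. = FALSE)
  structure(list(frequency_hz = frequency_hz), class = "fm_clock")
}

#' Frame index to time
#'
#' @param clock a [capture_clock()].
#' @param frame integer frame index (0-based in time: frame 0 is t = 0).
#' @return Time in seconds.
#' @export
frame_time <- function(clock, frame) {
  stopifnot(inherits(clock, "fm_clock"))
  frame / clock$frequency_hz
}

# Long-format trajectory table helpers -------------------------------------
#
# The canonical trajectory container is a long data.frame with columns
# (frame, time_s, label, x, y, z, n_cameras, gap, residual_px). `gap` is
# TRUE where the marker could not be placed in that frame (x/y/z are NA).

#' Validate a trajectory table
#'
#' @param traj a long trajectory data.frame.
#' @return `traj` invisibly; errors on malformed input.
#' @export
validate_trajectories <- function(traj) {
  need <- c("frame", "label", "x", "y", "z", "gap")
  miss <- setdiff(need, names(traj))
  if (length(miss))
    stop("trajectory table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- traj$gap | (is.finite(traj$x) & is.finite(traj$y) & is.finite(traj$z))
  if (!all(ok))
    stop("non-finite positions on non-gap frames (corrupted trajectory)",
         call. = FALSE)
  invisible(traj)
}

# positions of one label as a frames x 3 matrix ordered by frame
traj_matrix <- function(traj, label) {
  d <- traj[traj$label == label, , drop = FALSE]
  d <- d[order(d$frame), , drop = FALSE]
  m <- as.matrix(d[, c("x", "y", "z")])
  rownames(m) <- d$frame
  m
}
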