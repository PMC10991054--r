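#' Scene layout in normalized viewport coordinates
#'
#' Describes the static geometry of the task scene on a normalized viewport:
#' x runs from 0 (left) to 1 (right), y increases upward, and the target
#' always lands on a horizontal ground line at `ground_y`. The agent's two
#' eyes sit strictly above the ground line; each pupil can move on a circle
#' of radius `pupil_offset` around its eye center. For the continuous
#' ("hedge") version the ground line is divided into `n_bins` equal bins;
#' for the discrete ("box") version it is partitioned into `n_boxes` boxes.
#'
#' The default eye positions, pupil offset and target width are package
#' conventions: the task defines its stimuli as scalable vector graphics
#' that keep relative object positions constant, so only relative geometry
#' matters and no canonical pixel values exist.
#'
#' @param eye_centers Two-row numeric matrix (or list of two length-2
#'   vectors) of eye-center coordinates, one row per eye, columns x and y.
#' @param pupil_offset Distance from eye center to pupil center, in
#'   viewport-width units. Must be positive.
#' @param ground_y Height of the ground line the target lands on.
#' @param viewport_aspect Height/width ratio of the viewport (metadata;
#'   does not affect any computation on the x axis).
#' @param target_width Width of the target, in viewport-width units; the
#'   unit in which click imprecision is expressed.
#' @param n_bins Number of equal-width bins partitioning `[0, 1)` (hedge
#'   version).
#' @param n_boxes Number of boxes (box version), between 1 and 8.
#' @param box_edges Optional strictly increasing vector of box boundaries
#'   from 0 to 1 (length `n_boxes + 1`). Defaults to an equal partition.
#'
#' @return An object of class `scene_layout`.
#' @examples
#' layout <- scene_layout()
#' layout$box_edges
#' @export
scene_layout <- function(eye_centers = rbind(c(0.47, 0.65), c(0.53, 0.65)),
                         pupil_offset = 0.02,
                         ground_y = 0.1,
                         viewport_aspect = 0.75,
                         target_width = 0.05,
                         n_bins = 10,
                         n_boxes = 5,
                         box_edges = NULL) {
  if (is.list(eye_centers)) eye_centers <- do.call(rbind, eye_centers)
  eye_centers <- as.matrix(eye_centers)
  if (!is.numeric(eye_centers) || any(!is.finite(eye_centers)) ||
      ncol(eye_centers) != 2 || nrow(eye_centers) != 2) {
    abort("`eye_centers` must be two finite (x, y) points.")
  }
  colnames(eye_centers) <- c("x", "y")
  if (!is.numeric(pupil_offset) || pupil_offset <= 0) {
    abort("`pupil_offset` must be a positive length.")
  }
  if (!is.numeric(target_width) || target_width <= 0) {
    abort("`target_width` must be a positive length.")
  }
  if (any(eye_centers[, "y"] <= ground_y)) {
    abort("Eyes must lie strictly above the ground line.")
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 1) abort("`n_bins` must be at least 1.")
  n_boxes <- as.integer(n_boxes)
  if (n_boxes < 1 || n_boxes > 8) {
    abort("`n_boxes` must be between 1 and 8.")
  }
  if (is.null(box_edges)) {
    box_edges <- seq(0, 1, length.out = n_boxes + 1)
  }
  if (length(box_edges) != n_boxes + 1 || any(diff(box_edges) <= 0) ||
      box_edges[1] != 0 || box_edges[n_boxes + 1] != 1) {
    abort("`box_edges` must increase strictly from 0 to 1 with `n_boxes` + 1 values.")
  }
  structure(
    list(
      eye_centers = eye_centers,
      pupil_offset = pupil_offset,
      ground_y = ground_y,
      viewport_aspect = viewport_aspect,
      target_width = target_width,
      n_bins = n_bins,
      n_boxes = n_boxes,
      box_edges = as.numeric(box_edges)
    ),
    class = "scene_layout"
  )
}

#' @export
print.scene_layout <- function(x, ...) {
  cat("<scene_layout>\n")
  cat(sprintf("  eyes at (%.3f, %.3f), (%.3f, %.3f); pupil offset %.3f\n",
              x$eye_centers[1, 1], x$eye_centers[1, 2],
              x$eye_centers[2, 1], x$eye_centers[2, 2], x$pupil_offset))
  cat(sprintf("  ground y = %.3f, target width = %.3f, %d bins, %d boxes\n",
              x$ground_y, x$target_width, x$n_bins, x$n_boxes))
  invisible(x)
}

#' Place the pupils so that they fixate a target
#'
#' Forward gaze model: each pupil center is moved along the line from its
#' eye center toward the target, at distance `pupil_offset` from the eye
#' center, mirroring how the animated agent's pupil and iris centers align
#' with the target center.
#'
#' @param layout A [scene_layout()].
#' @param target Numeric length-2 vector `c(x, y)`, the fixated point.
#'   Must not coincide with an eye center.
#' @return An object of class `gaze_pose`: a list with `pupil_centers`,
#'   a two-row matrix of pupil-center coordinates.
#' @examples
#' pose_for_target(scene_layout(), c(0.2, 0.1))
#' @export
pose_for_target <- function(layout, target) {
  stopifnot(inherits(layout, "scene_layout"))
  target <- as.numeric(target)
  if (length(target) != 2 || any(!is.finite(target))) {
    abort("`target` must be a finite (x, y) point.")
  }
  d <- sweep(layout$eye_centers, 2, target, "-") * -1 # target - eye
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-12)) {
    abort("Degenerate geometry: target coincides with an eye center.")
  }
  pupils <- layout$eye_centers + layout$pupil_offset * d / len
  colnames(pupils) <- c("x", "y")
  structure(list(pupil_centers = pupils), class = "gaze_pose")
}

#' Invert a gaze pose to the cued ground position
#'
#' Ideal-observer inversion of the gaze cue: for each eye, the ray from the
#' eye center through its pupil center is extended until it meets the
#' ground line, and the mean of the two per-eye intersection x-coordinates
#' is returned. This is the computation the task asks of participants when
#' the target itself is hidden.
#'
#' @param layout A [scene_layout()].
#' @param pose A `gaze_pose`, e.g. from [pose_for_target()].
#' @return The inferred x-coordinate on the ground line.
#' @examples
#' layout <- scene_layout()
#' pose <- pose_for_target(layout, c(0.8, layout$ground_y))
#' infer_ground_x(layout, pose)
#' @export
infer_ground_x <- function(layout, pose) {
  stopifnot(inherits(layout, "scene_layout"), inherits(pose, "gaze_pose"))
  d <- pose$pupil_centers - layout$eye_centers
  if (any(d[, 2] >= 0)) {
    abort("Gaze ray does not point downward toward the ground line; no intersection.")
  }
  t <- (layout$ground_y - layout$eye_centers[, 2]) / d[, 2]
  mean(layout$eye_centers[, 1] + t * d[, 1])
}

#' Duration of the target's flight at constant speed
#'
#' The target travels from its start position to its landing position at a
#' constant speed, so flight duration is Euclidean distance over speed and
#' scales linearly with distance.
#'
#' @param start,end Numeric length-2 points in viewport units.
#' @param speed Positive speed in viewport units per second.
#' @return Duration in seconds.
#' @examples
#' flight_duration(c(0.5, 0.6), c(0.5, 0.0), speed = 0.3)
#' @export
flight_duration <- function(start, end, speed) {
  if (!is.numeric(speed) || length(speed) != 1 || speed <= 0) {
    abort("`speed` must be a single positive number.")
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  sqrt(sum((end - start)^2)) / speed
}
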