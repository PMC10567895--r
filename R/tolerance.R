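# Perspective-distortion tolerance for craniofacial superimposition.
#
# Superimposition practice accepts an FD mismatch when it changes the
# apparent physiognomical facial height by at most about 1%. The metric
# used here is the change in the projected-scale ratio between the nearest
# and farthest facial features contributing to face height, separated
# axially by a configurable depth extent. It is a declared stand-in for the
# criterion as operationalised in the superimposition literature (whose
# exact landmark/depth choices are not public); the depth extent has no
# canonical value and must be supplied (fixtures use a nominal 100 mm).

#' Facial depth model for perspective-tolerance checks
#'
#' @param depth_extent_mm Axial separation (mm) between the nearest and
#'   farthest facial features contributing to physiognomical face height.
#'   Nominal default 100 mm.
#' @return An object of class `"face_depth_model"`.
#' @export
face_depth_model <- function(depth_extent_mm = 100) {
  check_scalar_pos(depth_extent_mm, "depth_extent_mm")
  structure(list(depth_extent_mm = depth_extent_mm), class = "face_depth_model")
}

#' @export
print.face_depth_model <- function(x, ...) {
  cat(sprintf("<face_depth_model> depth extent = %g mm\n", x$depth_extent_mm))
  invisible(x)
}

#' Near/far projected-scale ratio at a focus distance
#'
#' The relative projected scale of the nearest vs the farthest facial
#' feature when photographed at `fd_mm`: `(fd + depth) / fd`. Tends to 1 as
#' the focus distance grows (the telephoto limit: perspective flattens with
#' distance).
#'
#' @param fd_mm Focus distance(s) in mm (> 0).
#' @param depth_model A [face_depth_model()].
#' @return Dimensionless ratio(s) > 1.
#' @export
perspective_ratio <- function(fd_mm, depth_model) {
  stopifnot(inherits(depth_model, "face_depth_model"))
  if (!is.numeric(fd_mm) || any(!is.finite(fd_mm)) || any(fd_mm <= 0)) {
    stop("invalid geometry: fd_mm must be positive and finite", call. = FALSE)
  }
  (fd_mm + depth_model$depth_extent_mm) / fd_mm
}

#' Percent change in apparent facial height implied by an FD mismatch
#'
#' Compares the perspective at the estimated focus distance against the
#' perspective at the true one:
#' `100 * |perspective_ratio(fd_est) / perspective_ratio(fd_true) - 1|`.
#' Zero exactly when the two distances agree. Swapping the arguments
#' changes the value only slightly (the ratio is inverted, not negated);
#' the convention is truth in the denominator.
#'
#' @param fd_true_mm,fd_est_mm True and estimated focus distances in mm.
#'   Vectorised.
#' @inheritParams perspective_ratio
#' @return Absolute percent change(s) in the near/far scale ratio.
#' @export
#' @examples
#' facial_height_change_pct(1000, 900, face_depth_model(100)) # ~1.01%
facial_height_change_pct <- function(fd_true_mm, fd_est_mm, depth_model) {
  100 * abs(perspective_ratio(fd_est_mm, depth_model) /
              perspective_ratio(fd_true_mm, depth_model) - 1)
}

#' Is an FD estimate within the perspective-distortion tolerance?
#'
#' The comparison is inclusive (`<=`): an estimate sitting exactly on the
#' threshold passes.
#'
#' @inheritParams facial_height_change_pct
#' @param threshold_pct Tolerance on the facial-height change, percent
#'   (default 1).
#' @return Logical vector.
#' @export
within_tolerance <- function(fd_true_mm, fd_est_mm, depth_model, threshold_pct = 1.0) {
  check_scalar_pos(threshold_pct, "threshold_pct")
  facial_height_change_pct(fd_true_mm, fd_est_mm, depth_model) <= threshold_pct
}
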