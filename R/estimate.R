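# Focus-distance estimators: frontal (palpebral fissure) and profile
# (pupil-chord-to-stomion, calibrated from a paired frontal photograph).

#' Anatomical priors for the known-length proxy
#'
#' The frontal estimator substitutes the population mean palpebral fissure
#' length `A` for the (unknowable) individual value; the small population
#' standard deviation of this trait (about 1.2 mm in adults) is what makes
#' the substitution usable. The mean is a configuration value, not a
#' constant: population-, sex- or ancestry-specific means can be supplied.
#'
#' @param mean_pfl_mm Population mean palpebral fissure length in mm
#'   (`A`). The shipped default of 30.7 mm is a nominal adult value from the
#'   anthropometric literature.
#' @param sd_pfl_mm Population standard deviation in mm (default 1.2).
#'   Used by the synthetic-subject generator and error-propagation analyses;
#'   the point estimator itself uses only the mean.
#' @return An object of class `"anatomical_priors"`.
#' @export
anatomical_priors <- function(mean_pfl_mm = 30.7, sd_pfl_mm = 1.2) {
  check_scalar_pos(mean_pfl_mm, "mean_pfl_mm")
  if (!is.numeric(sd_pfl_mm) || length(sd_pfl_mm) != 1L || !is.finite(sd_pfl_mm) || sd_pfl_mm < 0) {
    stop("sd_pfl_mm must be a single non-negative finite number", call. = FALSE)
  }
  if (sd_pfl_mm >= mean_pfl_mm) {
    stop("sd_pfl_mm must be smaller than mean_pfl_mm", call. = FALSE)
  }
  structure(list(mean_pfl_mm = mean_pfl_mm, sd_pfl_mm = sd_pfl_mm),
            class = "anatomical_priors")
}

#' @export
print.anatomical_priors <- function(x, ...) {
  cat(sprintf("<anatomical_priors> mean PFL = %g mm, SD = %g mm\n",
              x$mean_pfl_mm, x$sd_pfl_mm))
  invisible(x)
}

new_fd_estimate <- function(fd_mm, variant, view, inputs) {
  structure(list(fd_mm = fd_mm, model_variant = variant, view = view,
                 inputs = inputs),
            class = "fd_estimate")
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("<fd_estimate> %s view (%s model): FD = %s mm\n",
              x$view, x$model_variant,
              paste(formatC(x$fd_mm, format = "f", digits = 2), collapse = ", ")))
  invisible(x)
}

check_px <- function(px, what) {
  if (!is.numeric(px) || length(px) == 0L || any(!is.finite(px)) || any(px <= 0)) {
    stop("invalid measurement: ", what, " must be positive and finite", call. = FALSE)
  }
  invisible(px)
}

#' Estimate the focus distance of a frontal photograph
#'
#' Inverts the pinhole projection using the measured palpebral fissure
#' length in pixels (`x`), the lens focal length (`f`), the sensor pixel
#' pitch (`y`) and the population mean palpebral fissure length (`A`) as the
#' known-length proxy. Under the `"simple"` variant the estimate is
#' `fd = f * A / (x * y)`; under `"thin_lens"` the sensor-plane distance
#' solving the lens equation at magnification `x * y / A` is returned.
#'
#' @param pfl_px Measured palpebral fissure length in pixels (sub-pixel
#'   values allowed). Vectorised.
#' @param camera A [camera_spec()].
#' @param priors An [anatomical_priors()].
#' @param variant `"simple"` (default) or `"thin_lens"`; see
#'   [project_length()].
#' @return An `"fd_estimate"` object; `$fd_mm` holds the estimate(s) in mm.
#' @export
#' @examples
#' cam <- camera_spec("demo", focal_length_mm = 100, pixel_size_mm = 0.005)
#' estimate_fd_frontal(200, cam, anatomical_priors(30))$fd_mm # 3000 mm
estimate_fd_frontal <- function(pfl_px, camera, priors,
                                variant = c("simple", "thin_lens")) {
  variant <- match.arg(variant)
  stopifnot(is_camera_spec(camera), inherits(priors, "anatomical_priors"))
  check_px(pfl_px, "pfl_px")
  fd <- fd_from_px(pfl_px, priors$mean_pfl_mm,
                   camera$focal_length_mm, camera$pixel_size_mm, variant)
  new_fd_estimate(fd, variant, "frontal",
                  list(pfl_px = pfl_px, known_length_mm = priors$mean_pfl_mm,
                       focal_length_mm = camera$focal_length_mm,
                       pixel_size_mm = camera$pixel_size_mm))
}

#' Estimate the real-life pupil-chord-to-stomion length from a frontal photograph
#'
#' The mm-per-pixel scale implied by the fissure-length proxy is applied to
#' the pupil-chord-to-stomion pixel length measured on the *same* frontal
#' photograph: `pcs_mm = A * pcs_px / pfl_px`. Both features are treated as
#' lying in the same fronto-parallel plane. Both pixel lengths must come
#' from one photograph; this cannot be verified here and is the caller's
#' contract.
#'
#' @param pfl_px,pcs_px Palpebral fissure and pupil-chord-to-stomion pixel
#'   lengths from one frontal photograph. Vectorised.
#' @inheritParams estimate_fd_frontal
#' @return Estimated pupil-chord-to-stomion length(s) in mm.
#' @export
estimate_pcs_mm_from_frontal <- function(pfl_px, pcs_px, priors) {
  stopifnot(inherits(priors, "anatomical_priors"))
  check_px(pfl_px, "pfl_px")
  check_px(pcs_px, "pcs_px")
  priors$mean_pfl_mm * pcs_px / pfl_px
}

#' Estimate the focus distance of a profile photograph
#'
#' Same projection inversion as [estimate_fd_frontal()], with the
#' population-mean fissure length replaced by the subject-specific
#' pupil-chord-to-stomion estimate from a paired frontal photograph
#' ([estimate_pcs_mm_from_frontal()]).
#'
#' @param pcs_px_profile Pupil-chord-to-stomion pixel length measured on the
#'   profile photograph. Vectorised.
#' @param pcs_mm_est Estimated real-life pupil-chord-to-stomion length in mm.
#' @inheritParams estimate_fd_frontal
#' @return An `"fd_estimate"` object with `view = "profile"`.
#' @export
estimate_fd_profile <- function(pcs_px_profile, pcs_mm_est, camera,
                                variant = c("simple", "thin_lens")) {
  variant <- match.arg(variant)
  stopifnot(is_camera_spec(camera))
  check_px(pcs_px_profile, "pcs_px_profile")
  check_px(pcs_mm_est, "pcs_mm_est")
  fd <- fd_from_px(pcs_px_profile, pcs_mm_est,
                   camera$focal_length_mm, camera$pixel_size_mm, variant)
  new_fd_estimate(fd, variant, "profile",
                  list(pcs_px = pcs_px_profile, known_length_mm = pcs_mm_est,
                       focal_length_mm = camera$focal_length_mm,
                       pixel_size_mm = camera$pixel_size_mm))
}

as_measurement_row <- function(x, what) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop(what, " must be a single measurement row", call. = FALSE)
    x <- as.list(x)
  }
  if (!is.list(x)) stop(what, " must be a measurement row (list or one-row data frame)", call. = FALSE)
  x
}

field_ok <- function(x) !is.null(x) && length(x) == 1L && is.finite(x) && x > 0

#' Estimate focus distances for a frontal/profile photograph pair
#'
#' Chains the frontal estimator, the frontal-calibrated
#' pupil-chord-to-stomion scale transfer and the profile estimator for a
#' pair of photographs of one subject taken with the same camera/lens
#' combination at the same (unknown) focus distance.
#'
#' @param frontal,profile Measurement rows (one-row data frames or named
#'   lists) with fields `camera_name`, `pfl_px` (frontal), `pcs_px` (both).
#' @inheritParams estimate_fd_frontal
#' @return A list with elements `frontal` and `profile` (both
#'   `"fd_estimate"` objects) and `pcs_mm_est`, the intermediate
#'   pupil-chord-to-stomion length estimate in mm.
#' @export
estimate_pair <- function(frontal, profile, camera, priors,
                          variant = c("simple", "thin_lens")) {
  variant <- match.arg(variant)
  frontal <- as_measurement_row(frontal, "frontal")
  profile <- as_measurement_row(profile, "profile")
  if (!identical(frontal$camera_name, profile$camera_name)) {
    stop("pairing error: frontal and profile measurements come from different cameras (",
         frontal$camera_name, " vs ", profile$camera_name, ")", call. = FALSE)
  }
  if (!field_ok(frontal$pfl_px) || !field_ok(frontal$pcs_px)) {
    stop("invalid measurement: frontal row needs positive pfl_px and pcs_px", call. = FALSE)
  }
  if (!field_ok(profile$pcs_px)) {
    stop("invalid measurement: profile row needs positive pcs_px", call. = FALSE)
  }
  fd_frontal <- estimate_fd_frontal(frontal$pfl_px, camera, priors, variant)
  pcs_mm <- estimate_pcs_mm_from_frontal(frontal$pfl_px, frontal$pcs_px, priors)
  fd_profile <- estimate_fd_profile(profile$pcs_px, pcs_mm, camera, variant)
  list(frontal = fd_frontal, profile = fd_profile, pcs_mm_est = pcs_mm)
}
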