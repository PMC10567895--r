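# Synthetic subjects and photographs (as landmark pixel measurements).
#
# The simulator emulates the measurement side of a validation study: true
# anatomical lengths drawn from population distributions, projected to
# sensor pixels through the pinhole model, then degraded by landmark
# placement jitter and pixel-grid quantization. Noise is applied to the
# derived pixel *lengths*, not to 2D landmark coordinates - a documented
# simplification that is sufficient to reproduce the error structure of
# interest (resolution-limited measurement at long focus distances).

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Measurement noise model
#'
#' @param landmark_jitter_sd_px Standard deviation (pixels) of Gaussian
#'   jitter added to each measured pixel length, emulating landmark
#'   placement uncertainty. Default 0.5 px; 0 disables jitter.
#' @param quantize Round measured lengths to the pixel grid (default
#'   `TRUE`). Disable for sub-pixel ("ruler-tool") measurement.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(landmark_jitter_sd_px = 0.5, quantize = TRUE) {
  if (!is.numeric(landmark_jitter_sd_px) || length(landmark_jitter_sd_px) != 1L ||
      !is.finite(landmark_jitter_sd_px) || landmark_jitter_sd_px < 0) {
    stop("landmark_jitter_sd_px must be a single non-negative number", call. = FALSE)
  }
  stopifnot(is.logical(quantize), length(quantize) == 1L)
  structure(list(landmark_jitter_sd_px = landmark_jitter_sd_px, quantize = quantize),
            class = "noise_model")
}

rnorm_positive <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) { # redraw-on-non-positive truncation; negligible when mean >> sd
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Draw synthetic subjects
#'
#' Subjects carry a true palpebral fissure length drawn from the
#' anatomical-prior distribution `Normal(A, sd)` and a true
#' pupil-chord-to-stomion length drawn from a configurable normal.
#' Non-positive draws are redrawn (negligible probability at the default
#' mean-to-SD ratios).
#'
#' @param n Number of subjects (>= 1).
#' @param priors An [anatomical_priors()].
#' @param pcs_mean_mm,pcs_sd_mm Pupil-chord-to-stomion distribution in mm;
#'   defaults 65 and 3.5 (nominal adult eye-line-to-mouth distance).
#' @param seed Optional integer seed; the draw is reproducible given the
#'   seed and leaves the global RNG state untouched.
#' @return A tibble with columns `subject_id` (1..n), `pfl_true_mm`,
#'   `pcs_true_mm`.
#' @export
sample_subjects <- function(n, priors, pcs_mean_mm = 65, pcs_sd_mm = 3.5, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  stopifnot(inherits(priors, "anatomical_priors"))
  check_scalar_pos(pcs_mean_mm, "pcs_mean_mm")
  stopifnot(pcs_sd_mm >= 0)
  n <- as.integer(n)
  with_seed_maybe(seed, {
    pfl <- rnorm_positive(n, priors$mean_pfl_mm, priors$sd_pfl_mm)
    pcs <- rnorm_positive(n, pcs_mean_mm, pcs_sd_mm)
    tibble::tibble(subject_id = seq_len(n), pfl_true_mm = pfl, pcs_true_mm = pcs)
  })
}

apply_noise <- function(px, noise) {
  if (noise$landmark_jitter_sd_px > 0) {
    px <- px + stats::rnorm(length(px), 0, noise$landmark_jitter_sd_px) *
      as.numeric(!is.na(px))
  }
  if (noise$quantize) px <- round(px)
  # a measured length can never collapse below one pixel
  pmax(px, 1)
}

#' Simulate landmark pixel measurements for an acquisition design
#'
#' Resolves every design row to a subject and a camera specification,
#' projects the subject's true landmark lengths to sensor pixels at the
#' row's distance ([project_length()] geometry), and applies the noise
#' model. Frontal rows get both `pfl_px` and `pcs_px`; profile rows get
#' `pcs_px` only. The profile pose is not modelled geometrically; the
#' pupil-chord-to-stomion feature is treated as fronto-parallel in both
#' views, with an optional scalar foreshortening factor for sensitivity
#' analyses.
#'
#' @param design A design tibble ([build_dslr_design()],
#'   [build_smartphone_design()]).
#' @param subjects A subject tibble ([sample_subjects()]); `participant_id`
#'   values in the design must match `subject_id` values.
#' @param cameras A list of [camera_spec()] objects covering every
#'   `camera_name` in the design.
#' @param noise A [noise_model()].
#' @param seed Optional integer seed (reproducible, RNG-state safe).
#' @param variant Projection variant, `"simple"` (default) or `"thin_lens"`.
#' @param profile_foreshortening Scalar multiplier on the projected
#'   profile-view pupil-chord-to-stomion length (default 1: no
#'   foreshortening).
#' @return A measurement tibble (schema of [validate_measurements()]) with
#'   the design columns carried along as extra columns.
#' @export
simulate_measurements <- function(design, subjects, cameras, noise = noise_model(),
                                  seed = NULL, variant = c("simple", "thin_lens"),
                                  profile_foreshortening = 1) {
  variant <- match.arg(variant)
  stopifnot(inherits(noise, "noise_model"))
  check_scalar_pos(profile_foreshortening, "profile_foreshortening")
  lk <- camera_lookup(cameras)
  unknown <- setdiff(unique(design$camera_name), lk$name)
  if (length(unknown)) {
    stop("config error: no camera specification for: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  si <- match(design$participant_id, subjects$subject_id)
  if (anyNA(si)) {
    stop("config error: design references unknown participant(s): ",
         paste(unique(design$participant_id[is.na(si)]), collapse = ", "), call. = FALSE)
  }
  ci <- match(design$camera_name, lk$name)
  f <- lk$f[ci]
  y <- lk$y[ci]
  is_front <- design$view == "frontal"

  pfl_px <- rep(NA_real_, nrow(design))
  pfl_px[is_front] <- px_from_mm(subjects$pfl_true_mm[si[is_front]],
                                 design$distance_mm[is_front],
                                 f[is_front], y[is_front], variant)
  pcs_true <- subjects$pcs_true_mm[si] *
    ifelse(is_front, 1, profile_foreshortening)
  pcs_px <- px_from_mm(pcs_true, design$distance_mm, f, y, variant)

  with_seed_maybe(seed, {
    pfl_px[is_front] <- apply_noise(pfl_px[is_front], noise)
    pcs_px <- apply_noise(pcs_px, noise)
  })

  out <- tibble::tibble(
    subject_id = design$participant_id,
    camera_name = design$camera_name,
    view = design$view,
    pfl_px = pfl_px,
    pcs_px = pcs_px,
    fd_true_mm = design$distance_mm,
    replicate_id = design$replicate
  )
  extras <- setdiff(names(design), c("participant_id", "camera_name", "view", "replicate"))
  dplyr::bind_cols(out, design[, extras, drop = FALSE])
}
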