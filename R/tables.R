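# Table-level estimation over measurement data frames.

measurement_required_cols <- c("subject_id", "camera_name", "view",
                               "pfl_px", "pcs_px", "fd_true_mm", "replicate_id")

normalize_view <- function(view) {
  v <- tolower(trimws(as.character(view)))
  bad <- !v %in% c("frontal", "profile")
  if (any(bad)) {
    stop("unknown view value(s): ", paste(unique(view[bad]), collapse = ", "),
         " (expected frontal or profile)", call. = FALSE)
  }
  v
}

#' Validate a measurement table
#'
#' Checks the measurement schema: required columns present, views
#' normalisable to `frontal`/`profile`, positive pixel lengths where the
#' view requires them (frontal rows need `pfl_px`, profile rows need
#' `pcs_px`) and positive ground-truth distances where recorded. Unknown
#' extra columns are allowed and preserved by all pipeline stages.
#'
#' @param measurements A data frame.
#' @param source Optional label (e.g. a file name) used in error messages.
#' @return The validated table as a tibble, with `view` normalised.
#' @export
validate_measurements <- function(measurements, source = "measurements") {
  missing_cols <- setdiff(measurement_required_cols, names(measurements))
  if (length(missing_cols)) {
    stop("schema error in ", source, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- tibble::as_tibble(measurements)
  m$view <- normalize_view(m$view)
  for (col in c("pfl_px", "pcs_px", "fd_true_mm")) m[[col]] <- as.numeric(m[[col]])

  bad_frontal <- m$view == "frontal" & (is.na(m$pfl_px) | m$pfl_px <= 0)
  if (any(bad_frontal)) {
    stop("schema error in ", source, ": frontal row(s) ",
         paste(utils::head(which(bad_frontal), 5), collapse = ", "),
         " have missing or non-positive pfl_px", call. = FALSE)
  }
  bad_profile <- m$view == "profile" & (is.na(m$pcs_px) | m$pcs_px <= 0)
  if (any(bad_profile)) {
    stop("schema error in ", source, ": profile row(s) ",
         paste(utils::head(which(bad_profile), 5), collapse = ", "),
         " have missing or non-positive pcs_px", call. = FALSE)
  }
  bad_fd <- !is.na(m$fd_true_mm) & m$fd_true_mm <= 0
  if (any(bad_fd)) {
    stop("schema error in ", source, ": non-positive fd_true_mm on row(s) ",
         paste(utils::head(which(bad_fd), 5), collapse = ", "), call. = FALSE)
  }
  m
}

#' Select one measurement per station and view from duplicate exposures
#'
#' Acquisition protocols shoot duplicate exposures at every station
#' (subject x camera x distance) to protect against blinking. This mirrors
#' the analyst's "best image" choice with an explicit, deterministic rule:
#' rows whose view-required pixel field is missing are dropped, then the
#' first remaining row per station and view in `replicate_id` order is kept.
#'
#' @param measurements A measurement table (see [validate_measurements()]).
#' @param station_keys Columns identifying a station. Defaults to
#'   `subject_id`, `camera_name` and `fd_true_mm`.
#' @return The selected rows, one per station and view.
#' @export
select_best_replicate <- function(measurements,
                                  station_keys = c("subject_id", "camera_name", "fd_true_mm")) {
  station_keys <- intersect(station_keys, names(measurements))
  usable <- ifelse(measurements$view == "frontal",
                   !is.na(measurements$pfl_px) & measurements$pfl_px > 0,
                   !is.na(measurements$pcs_px) & measurements$pcs_px > 0)
  m <- measurements[usable, , drop = FALSE]
  m <- dplyr::arrange(m, dplyr::across(dplyr::all_of(c(station_keys, "view", "replicate_id"))))
  dplyr::distinct(m, dplyr::across(dplyr::all_of(c(station_keys, "view"))),
                  .keep_all = TRUE)
}

camera_lookup <- function(cameras) {
  if (is_camera_spec(cameras)) cameras <- list(cameras)
  stopifnot(is.list(cameras), all(vapply(cameras, is_camera_spec, logical(1))))
  nm <- vapply(cameras, function(c) c$name, character(1))
  list(name = nm,
       f = vapply(cameras, function(c) c$focal_length_mm, numeric(1)),
       y = vapply(cameras, function(c) c$pixel_size_mm, numeric(1)))
}

#' Estimate focus distances for every photograph in a measurement table
#'
#' Applies replicate selection ([select_best_replicate()]), estimates the FD
#' of every frontal photograph from its palpebral fissure length, transfers
#' the frontal-calibrated pupil-chord-to-stomion scale to the paired profile
#' photograph at the same station, and estimates profile FDs. Profile rows
#' without a frontal partner at their station get `NA` estimates (with a
#' message).
#'
#' @param measurements A measurement table; validated on entry.
#' @param cameras A list of [camera_spec()] objects covering every
#'   `camera_name` in the table.
#' @param priors An [anatomical_priors()].
#' @param variant `"simple"` (default) or `"thin_lens"`.
#' @param station_keys Columns pairing frontal and profile rows; see
#'   [select_best_replicate()].
#' @return A tibble with one row per selected photograph: all input columns
#'   plus `pcs_mm_est` (profile scale calibration, mm), `fd_est_mm` and
#'   `model_variant`.
#' @export
add_fd_estimates <- function(measurements, cameras, priors,
                             variant = c("simple", "thin_lens"),
                             station_keys = c("subject_id", "camera_name", "fd_true_mm")) {
  variant <- match.arg(variant)
  stopifnot(inherits(priors, "anatomical_priors"))
  m <- validate_measurements(measurements)
  station_keys <- intersect(station_keys, names(m))
  m <- select_best_replicate(m, station_keys)

  lk <- camera_lookup(cameras)
  unknown <- setdiff(unique(m$camera_name), lk$name)
  if (length(unknown)) {
    stop("no camera specification for: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ci <- match(m$camera_name, lk$name)
  f <- lk$f[ci]
  y <- lk$y[ci]
  A <- priors$mean_pfl_mm

  frontal <- m[m$view == "frontal", , drop = FALSE]
  profile <- m[m$view == "profile", , drop = FALSE]
  fi <- ci[m$view == "frontal"]
  pri <- ci[m$view == "profile"]

  frontal$fd_est_mm <- fd_from_px(frontal$pfl_px, A, lk$f[fi], lk$y[fi], variant)
  frontal$pcs_mm_est <- ifelse(!is.na(frontal$pcs_px) & frontal$pcs_px > 0,
                               A * frontal$pcs_px / frontal$pfl_px, NA_real_)

  calib <- frontal[, c(station_keys, "pcs_mm_est")]
  profile <- dplyr::left_join(profile, calib, by = station_keys)
  if (anyNA(profile$pcs_mm_est)) {
    message(sum(is.na(profile$pcs_mm_est)),
            " profile row(s) lack a frontal calibration partner; their fd_est_mm is NA")
  }
  profile$fd_est_mm <- fd_from_px(profile$pcs_px, profile$pcs_mm_est,
                                  lk$f[pri], lk$y[pri], variant)

  out <- dplyr::bind_rows(frontal, profile)
  out$model_variant <- variant
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(station_keys, "view"))))
}
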