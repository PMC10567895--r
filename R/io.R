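# Readers and writers: measurement/estimate CSVs and YAML configuration.
#
# CSV dialect: comma-separated, UTF-8, header required, RFC-4180 quoting,
# dot decimal separator regardless of locale. Every file written by the
# pipeline starts with a '#' provenance comment line (package version,
# seed, config hash); readers skip comment lines.

#' Read a measurement table from CSV
#'
#' Requires the header columns `subject_id`, `camera_name`, `view`,
#' `pfl_px`, `pcs_px`, `fd_true_mm`, `replicate_id` (missing numeric fields
#' are empty cells, not zeros). View labels are case-normalised
#' (`"Frontal"` -> `"frontal"`). Unknown extra columns are preserved.
#' Schema violations raise errors naming the file and offending column or
#' rows.
#'
#' @param path Path to a CSV file.
#' @return A validated measurement tibble ([validate_measurements()]).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  validate_measurements(df, source = path)
}

provenance_line <- function(seed = NULL, config_hash = NULL) {
  paste0(
    "# facefd ", as.character(utils::packageVersion("facefd")),
    if (!is.null(seed)) paste0(" seed=", seed) else "",
    if (!is.null(config_hash)) paste0(" config=", config_hash) else ""
  )
}

write_csv_provenance <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_line(seed, config_hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Write a measurement or estimate table to CSV
#'
#' Writes RFC-4180 CSV preceded by a `#` provenance comment line carrying
#' the package version and, when supplied, the seed and configuration hash
#' of the run that produced the table. [read_measurements()] and base
#' `read.csv(comment.char = "#")` both skip the comment.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param seed,config_hash Optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(rows, path, seed = NULL, config_hash = NULL) {
  stopifnot(is.data.frame(rows))
  write_csv_provenance(rows, path, seed, config_hash)
}

#' @rdname write_estimates
#' @export
write_measurements <- write_estimates

camera_spec_from_entry <- function(entry) {
  nm <- entry$name
  if (is.null(nm)) stop("config error: camera entry without a name", call. = FALSE)
  y_mm <- if (!is.null(entry$pixel_size_mm)) entry$pixel_size_mm
          else if (!is.null(entry$pixel_size_um)) entry$pixel_size_um / 1000
          else stop("config error: camera '", nm, "' needs pixel_size_um or pixel_size_mm",
                    call. = FALSE)
  f_mm <- entry$focal_length_mm
  if (is.null(f_mm)) {
    if (is.null(entry$equivalent_focal_length_mm) || is.null(entry$sensor_diagonal_mm)) {
      stop("config error: camera '", nm, "' needs focal_length_mm, or ",
           "equivalent_focal_length_mm together with sensor_diagonal_mm", call. = FALSE)
    }
    f_mm <- actual_focal_from_equivalent(entry$equivalent_focal_length_mm,
                                         entry$sensor_diagonal_mm)
  }
  camera_spec(nm, f_mm, y_mm,
              sensor_diagonal_mm = entry$sensor_diagonal_mm,
              resolution_px = if (!is.null(entry$resolution_px)) unlist(entry$resolution_px))
}

#' Read camera specifications from a YAML config
#'
#' Expects a top-level `cameras:` list; each entry has `name`, a pixel
#' pitch (`pixel_size_um`, converted to mm at load, or `pixel_size_mm`),
#' and a focal length - either `focal_length_mm` directly or
#' `equivalent_focal_length_mm` together with `sensor_diagonal_mm` (the
#' 35 mm-equivalent conversion of [actual_focal_from_equivalent()]).
#' Out-of-range pixel pitches are rejected at load.
#'
#' @param path Path to a YAML file.
#' @return A named list of [camera_spec()] objects.
#' @export
read_camera_config <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cameras)) {
    stop("config error: '", path, "' has no top-level 'cameras' list", call. = FALSE)
  }
  specs <- lapply(cfg$cameras, camera_spec_from_entry)
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  specs
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Read a synthetic-study configuration
#'
#' Parses a study YAML (see `inst/extdata/study_dslr.yaml` and
#' `study_smartphone.yaml` for the shipped designs) into a ready-to-run
#' configuration: distances converted from metres to millimetres, priors
#' and noise models constructed, and one [camera_spec()] per body/lens or
#' phone/position combination.
#'
#' @param path Path to a study YAML file.
#' @return An object of class `"study_config"`: a list consumed by
#'   [run_pipeline()] and the stage functions it chains.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  type <- cfg$study
  if (is.null(type) || !type %in% c("dslr", "smartphone")) {
    stop("config error: 'study' must be \"dslr\" or \"smartphone\"", call. = FALSE)
  }
  priors <- anatomical_priors(cfg$priors$mean_pfl_mm, cfg$priors$sd_pfl_mm)
  noise <- noise_model(cfg$noise$landmark_jitter_sd_px, isTRUE(cfg$noise$quantize))
  out <- list(
    type = type,
    n_participants = cfg$n_participants,
    replicates = if (is.null(cfg$replicates)) 2 else cfg$replicates,
    priors = priors,
    pcs_mean_mm = cfg$pcs$mean_mm,
    pcs_sd_mm = cfg$pcs$sd_mm,
    noise = noise,
    depth_model = face_depth_model(cfg$depth_model$depth_extent_mm),
    threshold_pct = if (is.null(cfg$threshold_pct)) 1.0 else cfg$threshold_pct,
    model_variant = if (is.null(cfg$model_variant)) "simple" else cfg$model_variant,
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
    group_by = c("camera_body", "lens_label", "view", "distance_mm"),
    hash = config_hash(cfg)
  )
  if (type == "dslr") {
    out$bodies <- dplyr::bind_rows(lapply(cfg$bodies, function(b) {
      tibble::tibble(name = b$name, pixel_size_um = b$pixel_size_um,
                     sensor_width_mm = b$sensor_width_mm,
                     sensor_height_mm = b$sensor_height_mm,
                     megapixels = b$megapixels)
    }))
    out$lens_configs <- lapply(cfg$bodies, function(b) {
      dplyr::bind_rows(lapply(b$lenses, function(l) {
        tibble::tibble(lens_label = l$label, focal_length_mm = l$focal_length_mm)
      }))
    })
    names(out$lens_configs) <- out$bodies$name
    out$distances_mm <- unlist(cfg$distances_m) * 1000
    out$cameras <- dslr_camera_specs(out$bodies, out$lens_configs)
  } else {
    out$phones <- dplyr::bind_rows(lapply(cfg$phones, function(p) {
      dplyr::bind_rows(lapply(names(p$cameras), function(pos) {
        cam <- p$cameras[[pos]]
        tibble::tibble(phone = p$name, position = pos,
                       focal_length_mm = cam$focal_length_mm,
                       pixel_size_um = cam$pixel_size_um,
                       megapixels = cam$megapixels)
      }))
    }))
    out$front_distances_mm <- unlist(cfg$front_distances_m) * 1000
    out$back_distances_mm <- unlist(cfg$back_distances_m) * 1000
    out$dropouts <- if (length(cfg$dropouts)) {
      dplyr::bind_rows(lapply(cfg$dropouts, function(d) {
        tibble::tibble(participant_id = d$participant_id, camera_name = d$camera_name)
      }))
    } else NULL
    out$cameras <- smartphone_camera_specs(out$phones)
  }
  structure(out, class = "study_config")
}

#' Shipped study configurations
#'
#' Convenience loaders for the two fixture designs transcribed in
#' `inst/extdata/`: a three-body DSLR study (five focal-length
#' configurations per body, distances 1--10 m) and a five-phone smartphone
#' study (front cameras 0.2--1.3 m, back cameras 0.3--10 m, two
#' participant/camera dropouts).
#'
#' @return A `"study_config"` ([read_study_config()]).
#' @export
dslr_study_config <- function() read_study_config(fixture_path("study_dslr.yaml"))

#' @rdname dslr_study_config
#' @export
smartphone_study_config <- function() read_study_config(fixture_path("study_smartphone.yaml"))
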