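# Acquisition-design builders: deterministic enumeration of the photographs
# a validation protocol requires. Designs are pure functions of their
# configuration; no randomness enters until measurement simulation.

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "facefd")
  if (!nzchar(path)) stop("fixture config not found: ", file, call. = FALSE)
  path
}

#' DSLR camera bodies from the shipped study configuration
#'
#' Three full-frame bodies with their sensor dimensions and pixel pitches,
#' as transcribed in `inst/extdata/study_dslr.yaml`.
#'
#' @return A tibble with columns `name`, `pixel_size_um`, `sensor_width_mm`,
#'   `sensor_height_mm`, `megapixels`.
#' @export
dslr_bodies <- function() {
  cfg <- yaml::read_yaml(fixture_path("study_dslr.yaml"))
  dplyr::bind_rows(lapply(cfg$bodies, function(b) {
    tibble::tibble(name = b$name, pixel_size_um = b$pixel_size_um,
                   sensor_width_mm = b$sensor_width_mm,
                   sensor_height_mm = b$sensor_height_mm,
                   megapixels = b$megapixels)
  }))
}

#' DSLR lens configurations from the shipped study configuration
#'
#' Per body: three fixed prime lenses plus the two end-range focal lengths
#' of one variable zoom lens (labelled `zoom_min` / `zoom_max`), i.e. five
#' focal-length configurations per body.
#'
#' @return A named list (one entry per body) of tibbles with columns
#'   `lens_label` and `focal_length_mm`.
#' @export
dslr_lens_configs <- function() {
  cfg <- yaml::read_yaml(fixture_path("study_dslr.yaml"))
  out <- lapply(cfg$bodies, function(b) {
    dplyr::bind_rows(lapply(b$lenses, function(l) {
      tibble::tibble(lens_label = l$label, focal_length_mm = l$focal_length_mm)
    }))
  })
  names(out) <- vapply(cfg$bodies, function(b) b$name, character(1))
  out
}

combo_name <- function(body, focal_length_mm) {
  sprintf("%s_%gmm", body, focal_length_mm)
}

#' Camera specifications for every DSLR body/focal-length combination
#'
#' @param bodies A tibble as returned by [dslr_bodies()].
#' @param lens_configs A named list as returned by [dslr_lens_configs()].
#' @return A list of [camera_spec()] objects, named like `canon_6d_50mm`.
#' @export
dslr_camera_specs <- function(bodies = dslr_bodies(), lens_configs = dslr_lens_configs()) {
  specs <- list()
  for (i in seq_len(nrow(bodies))) {
    body <- bodies$name[i]
    diag <- sqrt(bodies$sensor_width_mm[i]^2 + bodies$sensor_height_mm[i]^2)
    lenses <- lens_configs[[body]]
    if (is.null(lenses)) stop("no lens configuration for body ", body, call. = FALSE)
    for (j in seq_len(nrow(lenses))) {
      nm <- combo_name(body, lenses$focal_length_mm[j])
      specs[[nm]] <- camera_spec(nm, lenses$focal_length_mm[j],
                                 bodies$pixel_size_um[i] / 1000,
                                 sensor_diagonal_mm = diag)
    }
  }
  specs
}

#' Smartphone camera table from the shipped study configuration
#'
#' Five phones; all have a rear (`back`) camera, four have a usable `front`
#' camera (one phone's front camera is omitted because its technical
#' specifications are unavailable).
#'
#' @return A tibble with columns `phone`, `position` (`front`/`back`),
#'   `focal_length_mm`, `pixel_size_um`, `megapixels`.
#' @export
smartphone_cameras <- function() {
  cfg <- yaml::read_yaml(fixture_path("study_smartphone.yaml"))
  dplyr::bind_rows(lapply(cfg$phones, function(p) {
    dplyr::bind_rows(lapply(names(p$cameras), function(pos) {
      cam <- p$cameras[[pos]]
      tibble::tibble(phone = p$name, position = pos,
                     focal_length_mm = cam$focal_length_mm,
                     pixel_size_um = cam$pixel_size_um,
                     megapixels = cam$megapixels)
    }))
  }))
}

#' Camera specifications for every smartphone camera
#'
#' @param phones A tibble as returned by [smartphone_cameras()].
#' @return A list of [camera_spec()] objects, named like `iphone_5_back`.
#' @export
smartphone_camera_specs <- function(phones = smartphone_cameras()) {
  specs <- list()
  for (i in seq_len(nrow(phones))) {
    nm <- paste(phones$phone[i], phones$position[i], sep = "_")
    specs[[nm]] <- camera_spec(nm, phones$focal_length_mm[i],
                               phones$pixel_size_um[i] / 1000)
  }
  specs
}

design_grid <- function(participants, body, lenses, distances_mm, views, replicates) {
  g <- expand.grid(
    replicate = seq_len(replicates),
    view = views,
    distance_mm = distances_mm,
    lens_row = seq_len(nrow(lenses)),
    participant_id = participants,
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    participant_id = g$participant_id,
    camera_body = body,
    lens_label = lenses$lens_label[g$lens_row],
    focal_length_mm = lenses$focal_length_mm[g$lens_row],
    camera_name = combo_name(body, lenses$focal_length_mm[g$lens_row]),
    distance_mm = g$distance_mm,
    view = g$view,
    replicate = g$replicate
  )
}

#' Enumerate a DSLR acquisition design
#'
#' Cartesian design over participants, camera bodies, lens configurations
#' (five per body: three primes plus zoom-min and zoom-max), distances,
#' views and duplicate exposures. With the shipped defaults this yields 120
#' photographs per camera body per participant (5 x 6 x 2 x 2) and 360
#' across the three bodies.
#'
#' @param n_participants Number of participants (>= 1).
#' @param cameras Character vector of body names; defaults to the shipped
#'   three-body fixture.
#' @param lens_configs Named list of lens tables per body
#'   ([dslr_lens_configs()]).
#' @param distances_mm Focus distances in mm; default
#'   `c(1, 2, 3, 4, 6, 10) * 1000`.
#' @param views Views photographed at each station; default both
#'   `frontal` and `profile`.
#' @param replicates Duplicate exposures per station and view (default 2,
#'   guarding against blinking).
#' @return A design tibble with one row per photograph: `participant_id`,
#'   `camera_body`, `lens_label`, `focal_length_mm`, `camera_name`,
#'   `distance_mm`, `view`, `replicate`. Deterministic row order.
#' @export
build_dslr_design <- function(n_participants = 10,
                              cameras = names(lens_configs),
                              lens_configs = dslr_lens_configs(),
                              distances_mm = c(1, 2, 3, 4, 6, 10) * 1000,
                              views = c("frontal", "profile"),
                              replicates = 2) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("config error: n_participants must be >= 1", call. = FALSE)
  }
  if (length(cameras) == 0) stop("config error: empty camera list", call. = FALSE)
  stopifnot(replicates >= 1, length(distances_mm) >= 1, length(views) >= 1)
  views <- normalize_view(views)
  parts <- lapply(cameras, function(body) {
    lenses <- lens_configs[[body]]
    if (is.null(lenses) || nrow(lenses) == 0) {
      stop("config error: no lens configuration for body ", body, call. = FALSE)
    }
    design_grid(seq_len(n_participants), body, lenses, distances_mm, views, replicates)
  })
  out <- dplyr::bind_rows(parts)
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c("participant_id", "camera_body"))))
}

#' Enumerate a smartphone acquisition design
#'
#' Front cameras are shot over a short-range distance set, back cameras over
#' a set reaching 10 m; each station carries the same views-by-replicates
#' block as the DSLR design. Individual (participant, camera) pairs can be
#' dropped to emulate missing photographs.
#'
#' @param n_participants Number of participants (0 allowed: empty design).
#' @param phones Smartphone camera table ([smartphone_cameras()]); phones
#'   lacking a front camera simply have no `front` rows.
#' @param front_distances_mm,back_distances_mm Distance sets in mm for
#'   front and back cameras; defaults are the shipped fixture sets
#'   (front 0.2--1.3 m, back 0.3 m--10 m).
#' @param views,replicates As in [build_dslr_design()].
#' @param dropouts Optional data frame with columns `participant_id` and
#'   `camera_name`; matching design rows are removed.
#' @return A design tibble in the same shape as [build_dslr_design()], with
#'   `camera_body` = phone and `lens_label` = camera position.
#' @export
build_smartphone_design <- function(n_participants = 10,
                                    phones = smartphone_cameras(),
                                    front_distances_mm = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.9, 1.1, 1.3) * 1000,
                                    back_distances_mm = c(0.3, 0.5, 0.7, 1, 2, 4, 6, 10) * 1000,
                                    views = c("frontal", "profile"),
                                    replicates = 2,
                                    dropouts = NULL) {
  if (!is.numeric(n_participants) || n_participants < 0) {
    stop("config error: n_participants must be >= 0", call. = FALSE)
  }
  if (!is.data.frame(phones) || nrow(phones) == 0) {
    stop("config error: empty phone list", call. = FALSE)
  }
  bad_pos <- setdiff(unique(phones$position), c("front", "back"))
  if (length(bad_pos)) {
    stop("config error: unknown camera position(s): ", paste(bad_pos, collapse = ", "),
         call. = FALSE)
  }
  views <- normalize_view(views)
  if (n_participants == 0) {
    return(tibble::tibble(participant_id = integer(0), camera_body = character(0),
                          lens_label = character(0), focal_length_mm = numeric(0),
                          camera_name = character(0), distance_mm = numeric(0),
                          view = character(0), replicate = integer(0)))
  }
  parts <- lapply(seq_len(nrow(phones)), function(i) {
    dist <- if (phones$position[i] == "front") front_distances_mm else back_distances_mm
    lens <- tibble::tibble(lens_label = phones$position[i],
                           focal_length_mm = phones$focal_length_mm[i])
    d <- design_grid(seq_len(n_participants), phones$phone[i], lens, dist, views, replicates)
    d$camera_name <- paste(phones$phone[i], phones$position[i], sep = "_")
    d
  })
  out <- dplyr::bind_rows(parts)
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(c("participant_id", "camera_body"))))
  if (!is.null(dropouts) && nrow(dropouts) > 0) {
    stopifnot(all(c("participant_id", "camera_name") %in% names(dropouts)))
    out <- dplyr::anti_join(out, dropouts[, c("participant_id", "camera_name")],
                            by = c("participant_id", "camera_name"))
  }
  out
}
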