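# Camera/lens optics: specifications and the pinhole projection model.

# Diagonal of the full-frame 36 x 24 mm format, used for 35 mm-equivalent
# focal-length conversion.
FULL_FRAME_DIAGONAL_MM <- sqrt(36^2 + 24^2)

check_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(what, " must be a single positive finite number", call. = FALSE)
  }
  invisible(x)
}

#' Camera and lens specification
#'
#' Bundles the optical parameters needed to convert between real-world
#' lengths and sensor pixel lengths: the lens focal length `f` and the
#' physical sensor pixel pitch `y`, both in millimetres. For interchangeable
#' lens cameras, create one spec per body/focal-length combination.
#'
#' @param name Text identifier, e.g. `"canon_6d_50mm"`.
#' @param focal_length_mm Lens focal length in mm (`f`). Must be positive.
#' @param pixel_size_mm Sensor pixel pitch in mm (`y`). Manufacturer specs
#'   quote micrometres; divide by 1000 (config loaders accept
#'   `pixel_size_um` and convert). Values outside the physically plausible
#'   0.0005--0.02 mm (0.5--20 um) range are rejected.
#' @param sensor_diagonal_mm Optional sensor diagonal in mm, needed only to
#'   convert 35 mm-equivalent focal lengths (see
#'   [actual_focal_from_equivalent()]).
#' @param resolution_px Optional `c(width, height)` in pixels.
#'
#' @return An object of class `"camera_spec"`.
#' @seealso [project_length()], [read_camera_config()]
#' @export
#' @examples
#' camera_spec("canon_6d_100mm", focal_length_mm = 100, pixel_size_mm = 0.00655)
camera_spec <- function(name, focal_length_mm, pixel_size_mm,
                        sensor_diagonal_mm = NULL, resolution_px = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("name must be a single non-empty string", call. = FALSE)
  }
  check_scalar_pos(focal_length_mm, "focal_length_mm")
  check_scalar_pos(pixel_size_mm, "pixel_size_mm")
  if (pixel_size_mm < 0.0005 || pixel_size_mm > 0.02) {
    stop(sprintf(
      "pixel_size_mm = %g mm is outside the plausible sensor pitch range [0.0005, 0.02] mm (0.5-20 um)",
      pixel_size_mm
    ), call. = FALSE)
  }
  if (!is.null(sensor_diagonal_mm)) check_scalar_pos(sensor_diagonal_mm, "sensor_diagonal_mm")
  if (!is.null(resolution_px)) {
    stopifnot(is.numeric(resolution_px), length(resolution_px) == 2L, all(resolution_px > 0))
  }
  structure(
    list(
      name = name,
      focal_length_mm = focal_length_mm,
      pixel_size_mm = pixel_size_mm,
      sensor_diagonal_mm = sensor_diagonal_mm,
      resolution_px = resolution_px
    ),
    class = "camera_spec"
  )
}

#' @export
print.camera_spec <- function(x, ...) {
  cat(sprintf(
    "<camera_spec> %s: f = %g mm, pixel pitch = %g um%s\n",
    x$name, x$focal_length_mm, x$pixel_size_mm * 1000,
    if (!is.null(x$sensor_diagonal_mm)) sprintf(", sensor diagonal = %g mm", x$sensor_diagonal_mm) else ""
  ))
  invisible(x)
}

#' Is an object a camera specification?
#' @param x Object to test.
#' @return `TRUE` for objects created by [camera_spec()].
#' @export
is_camera_spec <- function(x) inherits(x, "camera_spec")

# Vectorised projection cores shared by project_length() and the estimators.
# "simple": similar triangles with the lens-to-object distance identified
# with the focus distance (the d >> f approximation).
# "thin_lens": focus distance measured to the sensor plane, fd = d + v with
# 1/f = 1/d + 1/v and magnification m = v/d, giving fd = f (2 + m + 1/m).
px_from_mm <- function(true_length_mm, fd_mm, f_mm, y_mm, variant) {
  if (variant == "simple") {
    f_mm * true_length_mm / (fd_mm * y_mm)
  } else {
    q <- fd_mm / f_mm - 2
    if (any(q <= 2, na.rm = TRUE)) {
      stop("invalid geometry: thin-lens projection requires fd_mm > 4 * focal_length_mm",
           call. = FALSE)
    }
    m <- 2 / (q + sqrt(q^2 - 4)) # demagnifying root of m^2 - q m + 1 = 0
    m * true_length_mm / y_mm
  }
}

fd_from_px <- function(px, known_length_mm, f_mm, y_mm, variant) {
  if (variant == "simple") {
    f_mm * known_length_mm / (px * y_mm)
  } else {
    m <- px * y_mm / known_length_mm
    if (any(m >= 1, na.rm = TRUE)) {
      stop("invalid geometry: thin-lens magnification >= 1 (object inside twice the focal length)",
           call. = FALSE)
    }
    f_mm * (2 + m + 1 / m)
  }
}

#' Project a real-world length onto the sensor
#'
#' Forward pinhole model: the pixel length that a fronto-parallel feature of
#' known physical length subtends on the sensor when photographed at a given
#' focus distance. This is the exact inverse of [estimate_fd_frontal()]
#' under the same model variant.
#'
#' @param true_length_mm Physical feature length in mm (> 0). Vectorised.
#' @param fd_mm Focus distance in mm, measured from the image receptor
#'   (sensor) plane to the feature. Must exceed the focal length (`"simple"`)
#'   or four focal lengths (`"thin_lens"`, the closest distance at which the
#'   lens equation has a real demagnifying solution). Vectorised.
#' @param camera A [camera_spec()].
#' @param variant `"simple"` (similar triangles, the lens-to-object distance
#'   taken as `fd_mm`; the default) or `"thin_lens"` (`fd = d + v` with
#'   `1/f = 1/d + 1/v`).
#'
#' @return Real-valued (sub-pixel) pixel length(s).
#' @export
#' @examples
#' cam <- camera_spec("demo", focal_length_mm = 100, pixel_size_mm = 0.005)
#' project_length(30, 3000, cam) # 200 px
project_length <- function(true_length_mm, fd_mm, camera,
                           variant = c("simple", "thin_lens")) {
  variant <- match.arg(variant)
  stopifnot(is_camera_spec(camera))
  if (!is.numeric(true_length_mm) || any(!is.finite(true_length_mm)) || any(true_length_mm <= 0)) {
    stop("invalid geometry: true_length_mm must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(fd_mm) || any(!is.finite(fd_mm)) || any(fd_mm <= camera$focal_length_mm)) {
    stop("invalid geometry: fd_mm must exceed the focal length", call. = FALSE)
  }
  px_from_mm(true_length_mm, fd_mm, camera$focal_length_mm, camera$pixel_size_mm, variant)
}

#' Convert a 35 mm-equivalent focal length to an actual focal length
#'
#' Smartphone makers usually publish only the 35 mm-equivalent focal length.
#' The actual focal length follows from the ratio of the sensor diagonal to
#' the full-frame diagonal `sqrt(36^2 + 24^2) = 43.2666 mm`. Crop factors are
#' deliberately not accepted directly (manufacturers disagree on their
#' definition); convert a crop factor to a diagonal first.
#'
#' @param f35_mm 35 mm-equivalent focal length in mm (> 0). Vectorised.
#' @param sensor_diagonal_mm Physical sensor diagonal in mm (> 0). Vectorised.
#' @return Actual focal length(s) in mm: `f35 * diagonal / 43.2666`.
#' @export
#' @examples
#' actual_focal_from_equivalent(26, 7.06) # ~4.24 mm, a typical phone camera
actual_focal_from_equivalent <- function(f35_mm, sensor_diagonal_mm) {
  if (!is.numeric(f35_mm) || any(!is.finite(f35_mm)) || any(f35_mm <= 0)) {
    stop("f35_mm must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(sensor_diagonal_mm) || any(!is.finite(sensor_diagonal_mm)) ||
      any(sensor_diagonal_mm <= 0)) {
    stop("sensor_diagonal_mm must be positive and finite", call. = FALSE)
  }
  f35_mm * sensor_diagonal_mm / FULL_FRAME_DIAGONAL_MM
}
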