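# Shared fixtures: cameras, priors, and programmatically built EXIF JPEGs.

demo_camera <- function(f = 100, y = 0.005, name = "demo") {
  camera_spec(name, focal_length_mm = f, pixel_size_mm = y)
}

canon_6d_100 <- function() camera_spec("canon_6d_100mm", 100, 0.00655)

priors30 <- function(sd = 1.2) anatomical_priors(30, sd)

# --- minimal JPEG/EXIF byte stream builders ---------------------------------

u16_raw <- function(x, little) {
  b <- c(x %% 256, x %/% 256)
  if (!little) b <- rev(b)
  as.raw(b)
}

u32_raw <- function(x, little) {
  b <- c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, x %/% 16777216)
  if (!little) b <- rev(b)
  as.raw(b)
}

ifd_entry <- function(tag, type, count, value, little) {
  c(u16_raw(tag, little), u16_raw(type, little), u32_raw(count, little),
    u32_raw(value, little))
}

# A JPEG consisting of SOI + APP1(Exif) + EOI: IFD0 holds the Exif-IFD
# pointer; the Exif IFD holds FocalLength as an unsigned rational.
exif_jpeg_bytes <- function(focal_num, focal_den = 1, byte_order = "II") {
  little <- byte_order == "II"
  tiff <- c(
    charToRaw(byte_order), u16_raw(42, little), u32_raw(8, little),
    # IFD0 at offset 8: one entry pointing at the Exif IFD (offset 26)
    u16_raw(1, little), ifd_entry(0x8769, 4, 1, 26, little), u32_raw(0, little),
    # Exif IFD at offset 26: one entry, rational payload at offset 44
    u16_raw(1, little), ifd_entry(0x920A, 5, 1, 44, little), u32_raw(0, little),
    u32_raw(focal_num, little), u32_raw(focal_den, little)
  )
  payload <- c(charToRaw("Exif"), as.raw(c(0, 0)), tiff)
  c(as.raw(c(0xff, 0xd8)),
    as.raw(c(0xff, 0xe1)), u16_raw(length(payload) + 2, little = FALSE), payload,
    as.raw(c(0xff, 0xd9)))
}

plain_jpeg_bytes <- function() {
  # SOI + a non-EXIF comment segment + EOI
  com <- charToRaw("no metadata here")
  c(as.raw(c(0xff, 0xd8)),
    as.raw(c(0xff, 0xfe)), u16_raw(length(com) + 2, little = FALSE), com,
    as.raw(c(0xff, 0xd9)))
}

write_jpeg_fixture <- function(bytes) {
  path <- withr::local_tempfile(fileext = ".jpg", .local_envir = parent.frame())
  writeBin(bytes, path)
  path
}

# Small noiseless measurement pair for one subject/station.
noiseless_pair <- function(fd_mm, pfl_true, pcs_true, camera, subject_id = 1L) {
  pfl_px <- project_length(pfl_true, fd_mm, camera)
  pcs_px <- project_length(pcs_true, fd_mm, camera)
  list(
    frontal = tibble::tibble(subject_id = subject_id, camera_name = camera$name,
                             view = "frontal", pfl_px = pfl_px, pcs_px = pcs_px,
                             fd_true_mm = fd_mm, replicate_id = 1L),
    profile = tibble::tibble(subject_id = subject_id, camera_name = camera$name,
                             view = "profile", pfl_px = NA_real_, pcs_px = pcs_px,
                             fd_true_mm = fd_mm, replicate_id = 1L)
  )
}
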