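# Minimal EXIF FocalLength extraction from JPEG files.
#
# Only the FocalLength tag (0x920A, an unsigned rational in the Exif
# sub-IFD) is read; FocalLengthIn35mmFilm is deliberately ignored because
# interpreting it requires a sensor diagonal the file does not carry
# (see actual_focal_from_equivalent()). Both TIFF byte orders are handled.

exif_u16 <- function(raw, offset, little) {
  b <- as.integer(raw[offset + 1:2])
  if (little) b[1] + 256 * b[2] else b[2] + 256 * b[1]
}

exif_u32 <- function(raw, offset, little) {
  b <- as.numeric(raw[offset + 1:4])
  if (little) sum(b * 256^(0:3)) else sum(b * 256^(3:0))
}

# Find the value offset of `tag` in the IFD starting at `ifd` (offset into
# the TIFF block, 0-based). Returns NA when the tag is absent.
exif_find_tag <- function(tiff, ifd, tag, little) {
  if (ifd + 2 > length(tiff)) return(NA_real_)
  n <- exif_u16(tiff, ifd, little)
  for (i in seq_len(n)) {
    entry <- ifd + 2 + (i - 1) * 12
    if (entry + 12 > length(tiff)) return(NA_real_)
    if (exif_u16(tiff, entry, little) == tag) return(entry)
  }
  NA_real_
}

#' Read the EXIF focal length of a JPEG photograph
#'
#' Returns the `FocalLength` EXIF tag in millimetres when present, or `NA`
#' when the file carries no EXIF block or no focal-length tag. Estimation
#' never requires image files; this is a convenience for populating camera
#' configurations from casework photographs.
#'
#' @param image_path Path to a JPEG file.
#' @return Focal length in mm, or `NA_real_` if absent.
#' @export
read_exif_focal_length <- function(image_path) {
  if (!file.exists(image_path)) {
    stop("cannot read '", image_path, "': no such file", call. = FALSE)
  }
  raw <- readBin(image_path, "raw", n = file.info(image_path)$size)
  if (length(raw) < 4 || raw[1] != as.raw(0xff) || raw[2] != as.raw(0xd8)) {
    stop("cannot read '", image_path, "': not a JPEG stream", call. = FALSE)
  }

  # Walk JPEG segments looking for APP1/Exif.
  pos <- 2L
  tiff <- NULL
  while (pos + 4 <= length(raw)) {
    if (raw[pos + 1] != as.raw(0xff)) break
    marker <- as.integer(raw[pos + 2])
    if (marker == 0xd9 || marker == 0xda) break # EOI / start of scan
    seg_len <- exif_u16(raw, pos + 2, little = FALSE)
    if (seg_len < 2 || pos + 2 + seg_len > length(raw)) {
      stop("cannot read '", image_path, "': truncated JPEG segment", call. = FALSE)
    }
    if (marker == 0xe1 && seg_len >= 8 &&
        identical(rawToChar(raw[pos + 4 + 1:4]), "Exif")) {
      tiff <- raw[(pos + 4 + 6 + 1):(pos + 2 + seg_len)]
      break
    }
    pos <- pos + 2L + seg_len
  }
  if (is.null(tiff) || length(tiff) < 8) return(NA_real_)

  order_tag <- rawToChar(tiff[1:2])
  if (!order_tag %in% c("II", "MM")) return(NA_real_)
  little <- order_tag == "II"
  ifd0 <- exif_u32(tiff, 4, little)

  # FocalLength lives in the Exif sub-IFD pointed to by tag 0x8769.
  ptr_entry <- exif_find_tag(tiff, ifd0, 0x8769, little)
  if (is.na(ptr_entry)) return(NA_real_)
  exif_ifd <- exif_u32(tiff, ptr_entry + 8, little)

  fl_entry <- exif_find_tag(tiff, exif_ifd, 0x920A, little)
  if (is.na(fl_entry)) return(NA_real_)
  if (exif_u16(tiff, fl_entry + 2, little) != 5L) return(NA_real_) # not RATIONAL
  val_off <- exif_u32(tiff, fl_entry + 8, little)
  if (val_off + 8 > length(tiff)) return(NA_real_)
  num <- exif_u32(tiff, val_off, little)
  den <- exif_u32(tiff, val_off + 4, little)
  if (den == 0) return(NA_real_)
  num / den
}
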