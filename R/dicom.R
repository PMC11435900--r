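# Minimal single-frame CT DICOM codec (explicit VR, little endian).
#
# Supports exactly what a single axial CT slice needs: the standard
# 128-byte preamble + "DICM" magic, an explicit-VR little-endian file meta
# group, uncompressed 16-bit MONOCHROME2 pixel data, pixel spacing and the
# rescale slope/intercept.  Anything else (implicit VR, compressed transfer
# syntaxes, sequences with undefined length, multi-frame objects) is
# rejected with a clear error.

EXPLICIT_LE_UID <- "1.2.840.10008.1.2.1"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

raw_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                   endian = "little")
raw_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                   endian = "little")

dcm_pad <- function(value, vr) {
  if (length(value) %% 2L == 1L)
    value <- c(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  value
}

dcm_element <- function(group, element, vr, value) {
  value <- dcm_pad(value, vr)
  header <- c(raw_uint16(group), raw_uint16(element), charToRaw(vr))
  if (vr %in% LONG_VRS)
    c(header, as.raw(c(0L, 0L)), raw_uint32(length(value)), value)
  else
    c(header, raw_uint16(length(value)), value)
}

dcm_str <- function(group, element, vr, text)
  dcm_element(group, element, vr, charToRaw(text))
dcm_us <- function(group, element, x)
  dcm_element(group, element, "US", raw_uint16(x))

#' Write a CT slice as a single-frame DICOM file
#'
#' Explicit-VR little-endian, 16-bit signed MONOCHROME2 pixel data.  Stored
#' values are `(HU - intercept) / slope`, so reading the file back and
#' applying the rescale recovers the HU grid exactly for integer HU.
#'
#' @param slice a [ct_slice()]; pixel values must be integral HU.
#' @param path output path.
#' @param slope,intercept rescale transform stored in the file
#'   (default slope 1, intercept -1024, the common CT convention).
#' @return `path`, invisibly.
#' @export
write_dicom_ct <- function(slice, path, slope = 1, intercept = -1024) {
  stopifnot(inherits(slice, "ct_slice"))
  px <- slice$pixels
  stored <- round((px - intercept) / slope)
  if (any(stored < -32768) || any(stored > 32767))
    stop("stored values exceed the signed 16-bit range", call. = FALSE)
  # DICOM pixel order is row-major (top row first, left to right)
  pixel_bytes <- writeBin(as.integer(as.vector(t(stored))), raw(),
                          size = 2L, endian = "little")
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_str(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.8.498.1"),
    dcm_str(0x0002, 0x0010, "UI", EXPLICIT_LE_UID))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", raw_uint32(length(meta_body))),
            meta_body)
  dataset <- c(
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, nrow(px)),
    dcm_us(0x0028, 0x0011, ncol(px)),
    dcm_str(0x0028, 0x0030, "DS",
            sprintf("%.10g\\%.10g", slice$spacing[1], slice$spacing[2])),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0101, 16L),
    dcm_us(0x0028, 0x0102, 15L),
    dcm_us(0x0028, 0x0103, 1L),
    dcm_str(0x0028, 0x1052, "DS", sprintf("%.10g", intercept)),
    dcm_str(0x0028, 0x1053, "DS", sprintf("%.10g", slope)),
    dcm_element(0x7FE0, 0x0010, "OW", pixel_bytes))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

read_uint16_at <- function(r, i)
  readBin(r[i:(i + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
read_uint32_at <- function(r, i)
  readBin(r[i:(i + 3L)], "integer", size = 4L, endian = "little")

read_dicom_ct <- function(path) {
  r <- readBin(path, raw(), n = file.size(path))
  if (length(r) < 140L || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing preamble/DICM magic): ", path,
         call. = FALSE)
  pos <- 133L
  tags <- list()
  while (pos + 7L <= length(r)) {
    group <- read_uint16_at(r, pos)
    element <- read_uint16_at(r, pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported DICOM encoding (implicit VR?): ", path, call. = FALSE)
    if (vr %in% LONG_VRS) {
      len <- read_uint32_at(r, pos + 8L)
      body <- pos + 12L
    } else {
      len <- read_uint16_at(r, pos + 6L)
      body <- pos + 8L
    }
    if (len < 0L || len == 0xFFFFFFFF)
      stop("undefined-length DICOM elements are not supported", call. = FALSE)
    value <- if (len > 0L) r[body:(body + len - 1L)] else raw(0L)
    tags[[sprintf("%04x,%04x", group, element)]] <- list(vr = vr,
                                                         value = value)
    pos <- body + len
  }
  ts <- tags[["0002,0010"]]
  if (!is.null(ts) &&
      sub("\\s+$", "", rawToChar(ts$value)) != EXPLICIT_LE_UID)
    stop("unsupported transfer syntax: ", rawToChar(ts$value), call. = FALSE)
  need <- function(tag, what) {
    t <- tags[[tag]]
    if (is.null(t)) stop("DICOM file lacks ", what, call. = FALSE)
    t
  }
  nrow_px <- read_uint16_at(need("0028,0010", "Rows")$value, 1L)
  ncol_px <- read_uint16_at(need("0028,0011", "Columns")$value, 1L)
  bits <- read_uint16_at(need("0028,0100", "BitsAllocated")$value, 1L)
  if (bits != 16L) stop("only 16-bit pixel data is supported", call. = FALSE)
  signed <- TRUE
  pr <- tags[["0028,0103"]]
  if (!is.null(pr)) signed <- read_uint16_at(pr$value, 1L) == 1L
  frames <- tags[["0028,0008"]]
  if (!is.null(frames) &&
      as.integer(sub("\\s+$", "", rawToChar(frames$value))) > 1L)
    stop("multi-frame DICOM is not supported; extract one slice first",
         call. = FALSE)
  pd <- need("7fe0,0010", "PixelData")$value
  if (length(pd) < 2L * nrow_px * ncol_px)
    stop("PixelData is shorter than Rows x Columns", call. = FALSE)
  stored <- readBin(pd, "integer", n = nrow_px * ncol_px, size = 2L,
                    endian = "little", signed = signed)
  ds_num <- function(tag, default) {
    t <- tags[[tag]]
    if (is.null(t)) return(default)
    as.numeric(strsplit(sub("\\s+$", "", rawToChar(t$value)), "\\\\")[[1L]])
  }
  slope <- ds_num("0028,1053", 1)[1L]
  intercept <- ds_num("0028,1052", 0)[1L]
  spacing <- ds_num("0028,0030", NA)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    warning("DICOM pixel spacing missing; assuming ", DEFAULT_SPACING[1],
            " mm")
    spacing <- DEFAULT_SPACING
  }
  hu <- matrix(stored * slope + intercept, nrow = nrow_px, ncol = ncol_px,
               byrow = TRUE)
  ct_slice(hu, spacing = spacing, origin_note = paste0("dicom:", path))
}
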