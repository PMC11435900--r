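# Reading and writing CT slices and masks.
#
# Formats: NIfTI-1 (.nii/.nii.gz, via RNifti), single-frame explicit-VR
# little-endian DICOM (minimal reader/writer implemented here), PNG
# (8-bit masks and windowed previews; 16-bit HU storage for raw-image
# round trips).  All CT pixel values are on the Hounsfield scale: the DICOM
# rescale slope/intercept is applied exactly once, on read.

DEFAULT_SPACING <- c(1.27, 1.27)

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.dcm$|\\.ima$", low)) "dicom"
  else if (grepl("\\.nii$|\\.nii\\.gz$", low)) "nifti"
  else if (grepl("\\.png$", low)) "raw-image"
  else stop("cannot guess format from extension: ", path, call. = FALSE)
}

#' Read a CT slice
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"dicom"`, `"nifti"` or
#'   `"raw-image"` (two-channel HU PNG written by [write_ct()], or a 16-bit
#'   greyscale PNG storing `HU + 1024`).
#' @param slice slice index, required when a NIfTI file holds a volume.
#' @return A [ct_slice()] in HU.  When the file carries no pixel spacing,
#'   the reference 1.27 mm is assumed with a warning (never a silent 1.0:
#'   HD95/ASD are reported in mm).
#' @export
read_ct <- function(path, format = c("auto", "dicom", "nifti", "raw-image"),
                    slice = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    dicom = read_dicom_ct(path),
    nifti = {
      img <- RNifti::readNifti(path)
      arr <- as.array(img)
      if (length(dim(arr)) == 3L) {
        if (dim(arr)[3L] == 1L) arr <- arr[, , 1L]
        else if (is.null(slice))
          stop("NIfTI file holds ", dim(arr)[3L],
               " slices; give an explicit 'slice' index", call. = FALSE)
        else arr <- arr[, , slice]
      } else if (length(dim(arr)) != 2L)
        stop("unsupported NIfTI dimensionality", call. = FALSE)
      pd <- RNifti::pixdim(img)[1:2]
      if (any(!is.finite(pd)) || any(pd <= 0)) {
        warning("NIfTI pixel spacing missing; assuming ",
                DEFAULT_SPACING[1], " mm")
        pd <- DEFAULT_SPACING
      }
      ct_slice(arr, spacing = pd, origin_note = paste0("nifti:", path))
    },
    `raw-image` = {
      v <- png::readPNG(path)
      stored <- if (length(dim(v)) == 3L)
        round(v[, , 1L] * 255) * 256 + round(v[, , 2L] * 255)
      else
        round(v * 65535)   # 16-bit greyscale from external tools
      warning("PNG carries no pixel spacing; assuming ",
              DEFAULT_SPACING[1], " mm")
      ct_slice(stored - 1024, spacing = DEFAULT_SPACING,
               origin_note = paste0("png:", path))
    })
}

#' Write a CT slice
#'
#' @param slice a [ct_slice()].
#' @param path output path; extension selects the format unless given.
#' @param format `"auto"`, `"dicom"`, `"nifti"` or `"raw-image"` (a PNG
#'   storing `HU + 1024` split over two 8-bit channels, exact for integer
#'   HU in `[-1024, 64511]`).
#' @return `path`, invisibly.
#' @export
write_ct <- function(slice, path,
                     format = c("auto", "dicom", "nifti", "raw-image")) {
  stopifnot(inherits(slice, "ct_slice"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    dicom = write_dicom_ct(slice, path),
    nifti = {
      im <- RNifti::asNifti(slice$pixels)
      RNifti::pixdim(im) <- slice$spacing
      RNifti::writeNifti(im, path)
    },
    `raw-image` = {
      stored <- round(slice$pixels) + 1024
      if (any(stored < 0) || any(stored > 65535))
        stop("HU out of the PNG storable range [-1024, 64511]", call. = FALSE)
      # two 8-bit channels: R = high byte, G = low byte (writePNG is 8-bit)
      arr <- array(0, c(nrow(stored), ncol(stored), 3L))
      arr[, , 1L] <- (stored %/% 256) / 255
      arr[, , 2L] <- (stored %% 256) / 255
      png::writePNG(arr, target = path, dpi = NULL)
    })
  invisible(path)
}

#' Read a binary mask
#'
#' @param path PNG (any nonzero value is foreground) or NIfTI file.
#' @param foreground declared foreground code; required when the file holds
#'   more than two distinct values.
#' @param spacing pixel spacing in mm for formats that carry none (PNG).
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, foreground = NULL, spacing = DEFAULT_SPACING) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- guess_format(path)
  if (fmt == "raw-image") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v <- v[, , 1L]
    vals <- round(v * 255)
  } else if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    if (length(dim(vals)) == 3L && dim(vals)[3L] == 1L) vals <- vals[, , 1L]
    pd <- RNifti::pixdim(img)[1:2]
    if (all(is.finite(pd)) && all(pd > 0)) spacing <- pd
  } else stop("unsupported mask format: ", fmt, call. = FALSE)
  u <- unique(as.vector(vals))
  if (is.null(foreground)) {
    if (length(u) > 2L)
      stop("mask file holds ", length(u),
           " distinct values; declare a 'foreground' code", call. = FALSE)
    binary_mask(vals != 0, spacing)
  } else {
    binary_mask(vals == foreground, spacing)
  }
}

#' Write a binary mask
#'
#' PNG masks are stored as 8-bit 0/255; NIfTI masks as uint8 0/1 with the
#' mask's spacing.  Both dialects are accepted by [read_mask()], and the
#' round trip is lossless.
#'
#' @param mask a [binary_mask()].
#' @param path output path (.png, .nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  px <- as_mask_pixels(mask)
  fmt <- guess_format(path)
  if (fmt == "raw-image") {
    png::writePNG(array(as.numeric(px), dim(px)), target = path, dpi = NULL)
  } else if (fmt == "nifti") {
    im <- RNifti::asNifti(array(as.integer(px), dim(px)))
    RNifti::pixdim(im) <- mask_spacing(mask)
    RNifti::writeNifti(im, path, datatype = "uint8")
  } else stop("unsupported mask format: ", fmt, call. = FALSE)
  invisible(path)
}

#' Write a label map (PNG + legend sidecar)
#'
#' Class codes are stored directly in an 8-bit PNG (`code/255`), with a
#' tab-separated `<path>.legend.txt` sidecar mapping codes to class names.
#'
#' @param labels a [label_map()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  if (max(labels$pixels) > 255L)
    stop("label codes above 255 cannot be stored in an 8-bit PNG",
         call. = FALSE)
  png::writePNG(labels$pixels / 255, target = path, dpi = NULL)
  utils::write.table(
    data.frame(code = names(labels$legend), class = unname(labels$legend)),
    file = paste0(path, ".legend.txt"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path PNG path (the `.legend.txt` sidecar must sit next to it).
#' @param spacing pixel spacing in mm.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, spacing = DEFAULT_SPACING) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  codes <- array(as.integer(round(v * 255)), dim(v))
  legend_path <- paste0(path, ".legend.txt")
  legend <- if (file.exists(legend_path)) {
    tab <- utils::read.table(legend_path, header = TRUE, sep = "\t",
                             colClasses = "character")
    stats::setNames(tab$class, tab$code)
  } else l3_label_legend()
  label_map(codes, legend = legend, spacing = spacing)
}

#' Write an 8-bit windowed preview of a CT slice
#'
#' @param slice a [ct_slice()].
#' @param path output PNG path.
#' @param center,width window center and width in HU; default 40/400, the
#'   soft-tissue window.
#' @return `path`, invisibly.
#' @export
write_ct_preview <- function(slice, path, center = 40, width = 400) {
  stopifnot(inherits(slice, "ct_slice"))
  v <- (slice$pixels - (center - width / 2)) / width
  v[v < 0] <- 0; v[v > 1] <- 1
  png::writePNG(v, target = path, dpi = NULL)
  invisible(path)
}
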