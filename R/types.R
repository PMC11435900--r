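#' Construct a CT slice
#'
#' A `ct_slice` holds one axial CT image as a numeric matrix of Hounsfield
#' units (HU) together with its physical pixel spacing.  Pixels are indexed
#' `[row, col]`, 0 offsets from the image top; row 1 is the image top, which
#' corresponds to the anatomical anterior side in standard axial display.
#' Values must already be on the HU scale (air near -1000), i.e. any
#' rescale slope/intercept has been applied.
#'
#' @param pixels numeric matrix of HU values.
#' @param spacing numeric length-2, physical pixel size in mm as
#'   `c(row_mm, col_mm)`.  Both entries must be positive.
#' @param origin_note free-text provenance string.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, spacing = c(1.27, 1.27), origin_note = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) == 0L))
    stop("'pixels' must be a non-empty numeric matrix", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be two positive numbers (mm)", call. = FALSE)
  structure(list(pixels = pixels, spacing = spacing,
                 origin_note = as.character(origin_note)[1L]),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, spacing %.4g x %.4g mm, HU range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  if (nzchar(x$origin_note)) cat("  origin:", x$origin_note, "\n")
  invisible(x)
}

#' Construct a binary mask
#'
#' A `binary_mask` is a logical matrix aligned with a [ct_slice()]; it is
#' the working currency of every segmentation stage (body, candidate and
#' muscle masks).
#'
#' @param pixels logical matrix (or coercible 0/1 matrix).
#' @param spacing pixel spacing in mm, inherited from the paired slice.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, spacing = c(1.27, 1.27)) {
  if (!is.matrix(pixels) || any(dim(pixels) == 0L))
    stop("'pixels' must be a non-empty matrix", call. = FALSE)
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1)))
      stop("non-logical mask pixels must be 0/1", call. = FALSE)
    pixels <- array(as.logical(pixels), dim = dim(pixels))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("'spacing' must be two positive numbers (mm)", call. = FALSE)
  structure(list(pixels = pixels, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground (%.2f%%)\n",
              nrow(x$pixels), ncol(x$pixels), mask_area(x),
              100 * mask_area(x) / length(x$pixels)))
  invisible(x)
}

#' Foreground pixel count of a mask
#' @param mask a [binary_mask()].
#' @return integer count of foreground pixels.
#' @export
mask_area <- function(mask) sum(as_mask_pixels(mask))

#' Construct a label map
#'
#' A `label_map` assigns every pixel one small non-negative integer class
#' code; code 0 is background/air.  Used as phantom ground truth and for
#' multi-class consensus voting.
#'
#' @param pixels integer matrix of class codes.
#' @param legend named character vector mapping code (name) to class name,
#'   e.g. `c("0" = "air", "3" = "abdominal_muscle")`.
#' @param spacing pixel spacing in mm.
#' @return An object of class `label_map`.
#' @export
label_map <- function(pixels, legend = l3_label_legend(), spacing = c(1.27, 1.27)) {
  if (!is.matrix(pixels) || any(dim(pixels) == 0L))
    stop("'pixels' must be a non-empty matrix", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L)) stop("label codes must be non-negative", call. = FALSE)
  codes <- sort(unique(as.vector(pixels)))
  missing <- setdiff(as.character(codes), names(legend))
  if (length(missing))
    stop("codes absent from legend: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(pixels = pixels, legend = legend, spacing = as.numeric(spacing)),
            class = "label_map")
}

#' Default tissue class legend
#'
#' @return Named character vector of the tissue classes used by the phantom
#'   generator and the evaluation code.
#' @export
l3_label_legend <- function() {
  c("0" = "air", "1" = "skin", "2" = "fat", "3" = "abdominal_muscle",
    "4" = "paraspinal_muscle", "5" = "organ", "6" = "bone")
}

#' Extract a binary mask of one label class
#'
#' @param labels a [label_map()].
#' @param class class name (matched in the legend) or integer code.
#' @return A [binary_mask()] of the pixels carrying that class.
#' @export
label_class_mask <- function(labels, class) {
  stopifnot(inherits(labels, "label_map"))
  if (is.character(class)) {
    code <- as.integer(names(labels$legend)[labels$legend %in% class])
    if (!length(code)) stop("class not found in legend: ", class, call. = FALSE)
  } else code <- as.integer(class)
  binary_mask(array(labels$pixels %in% code, dim = dim(labels$pixels)),
              labels$spacing)
}

# Accept a binary_mask or a plain logical matrix and return logical matrix.
as_mask_pixels <- function(mask) {
  if (inherits(mask, "binary_mask")) return(mask$pixels)
  if (is.logical(mask) && is.matrix(mask)) return(mask)
  stop("expected a binary_mask or logical matrix", call. = FALSE)
}

same_shape <- function(a, b) identical(dim(as_mask_pixels2(a)), dim(as_mask_pixels2(b)))

as_mask_pixels2 <- function(x) {
  if (inherits(x, "binary_mask") || inherits(x, "label_map")) return(x$pixels)
  if (inherits(x, "ct_slice")) return(x$pixels)
  x
}

mask_spacing <- function(mask, default = c(1.27, 1.27)) {
  if (inherits(mask, "binary_mask") || inherits(mask, "ct_slice") ||
      inherits(mask, "label_map")) mask$spacing else default
}
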