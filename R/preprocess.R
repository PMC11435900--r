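# Preprocessing: global HU thresholding and distance-map skin removal.
#
# The global band keeps pixels in the standard skeletal-muscle HU range
# [-29, 150]; adipose tissue (about -100 HU) and bone (> 150 HU) fall
# outside it.  Skin, however, sits inside the muscle range, so it is peeled
# off geometrically: the isocontour of the body's Chebyshev distance map
# that crosses the most non-muscle pixels marks the depth of the
# subcutaneous fat, and everything superficial to it is removed.

#' Global HU band thresholding
#'
#' Foreground iff `lo <= HU <= hi` (closed interval).
#'
#' @param slice a [ct_slice()].
#' @param lo,hi lower/upper thresholds in HU; defaults -29 and 150, the
#'   standard skeletal-muscle CT number range.
#' @return A [binary_mask()].
#' @export
threshold_band <- function(slice, lo = -29, hi = 150) {
  stopifnot(inherits(slice, "ct_slice"))
  if (!(lo < hi)) stop("threshold band requires lo < hi", call. = FALSE)
  binary_mask(slice$pixels >= lo & slice$pixels <= hi, slice$spacing)
}

#' Extract the body region
#'
#' Largest 8-connected component of non-air pixels, with interior holes
#' filled (so bowel gas does not create spurious boundaries in the distance
#' map).
#'
#' @param slice a [ct_slice()].
#' @param air_hu HU threshold separating air from tissue; pixels strictly
#'   above it are non-air.  Default -500, the midpoint between air (-1000)
#'   and fat (about -100).
#' @return A [binary_mask()] of one connected, hole-free body region.
#' @export
extract_body <- function(slice, air_hu = -500) {
  stopifnot(inherits(slice, "ct_slice"))
  nonair <- slice$pixels > air_hu
  if (!any(nonair)) stop("slice contains no non-air pixels", call. = FALSE)
  body <- largest_component(binary_mask(nonair, slice$spacing), 8L)
  fill_holes(body)
}

#' Most probable distance of a distance map
#'
#' Finds the distance level whose isocontour (the pixels at exactly that
#' integer Chebyshev distance) intersects the highest number of
#' zero-valued (or one-valued) pixels of an indicator mask.  Ties are broken
#' toward the smallest level so the thinnest sufficient rim is selected.
#'
#' @param dmap a `distance_map` from [chebyshev_distance_map()].
#' @param indicator a [binary_mask()] of the same shape.
#' @param target `"zero"` to count indicator background pixels on each
#'   isocontour, `"one"` to count foreground pixels.
#' @param within optional [binary_mask()]; when given, only pixels inside it
#'   are counted.
#' @return Integer distance level `d* >= 1`.
#' @export
most_probable_distance <- function(dmap, indicator, target = c("zero", "one"),
                                   within = NULL) {
  stopifnot(inherits(dmap, "distance_map"))
  target <- match.arg(target)
  ind <- as_mask_pixels(indicator)
  if (!identical(dim(dmap$pixels), dim(ind)))
    stop("distance map and indicator shapes differ", call. = FALSE)
  d <- dmap$pixels
  keep <- d >= 1L
  if (!is.null(within)) keep <- keep & as_mask_pixels(within)
  if (!any(keep)) stop("distance map has no positive levels", call. = FALSE)
  match_val <- if (target == "zero") !ind else ind
  counts <- tabulate(d[keep & match_val], nbins = max(d))
  if (all(counts == 0L)) return(1L)   # no matching pixels on any isocontour
  which.max(counts)                   # which.max returns the smallest argmax
}

#' Remove skin tissue from the muscle-candidate mask
#'
#' Builds the Chebyshev distance map of the body, locates the isocontour
#' intersecting the most non-muscle (zero-valued) pixels of the globally
#' thresholded mask -- the depth of the subcutaneous fat -- and removes all
#' pixels at that distance or closer to the body surface.  Small remaining
#' components are then filtered out.
#'
#' @param body body region from [extract_body()].
#' @param muscle_band globally thresholded mask from [threshold_band()].
#' @param min_area_px area cut-off passed to [filter_small()].
#' @return A list with `mask` (the skin-removed candidate [binary_mask()],
#'   a subset of `muscle_band` and `body`), `body_interior` (body pixels
#'   deeper than the removed rim), `d_star` (the selected distance level)
#'   and `dmap` (the body distance map).
#' @export
remove_skin <- function(body, muscle_band, min_area_px = 20L) {
  bpx <- as_mask_pixels(body)
  mpx <- as_mask_pixels(muscle_band)
  if (!identical(dim(bpx), dim(mpx)))
    stop("body and muscle_band shapes differ", call. = FALSE)
  if (!any(bpx)) stop("body mask is empty", call. = FALSE)
  dmap <- chebyshev_distance_map(binary_mask(bpx, mask_spacing(body)),
                                 source = "body surface")
  d_star <- most_probable_distance(dmap, binary_mask(mpx, mask_spacing(body)),
                                   target = "zero")
  interior <- bpx & dmap$pixels > d_star
  kept <- mpx & interior
  mask <- filter_small(binary_mask(kept, mask_spacing(body)), min_area_px)
  list(mask = mask,
       body_interior = binary_mask(interior, mask_spacing(body)),
       d_star = d_star, dmap = dmap)
}
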