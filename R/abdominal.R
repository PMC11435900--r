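# Abdominal wall segmentation: the thin anterolateral muscle band is the
# outermost candidate structure, so the convex hull of the skin-removed
# candidates traces its outer surface.  A Chebyshev distance map seeded at
# the hull boundary then measures depth below that surface; the isocontour
# crossing the most non-candidate pixels marks the band's inner boundary,
# and iterative removal of convex hulls of interior dark regions trims
# whatever bulges into the band (bowel gas, organs).

#' Identify the abdominal muscle band
#'
#' Builds the convex hull of the skin-removed candidate mask, computes the
#' Chebyshev distance map from the hull boundary, finds the most probable
#' distance `d*` (isocontour with the most zero-valued pixels inside the
#' hull) and removes all pixels at distance `>= d*` ("inside and on the
#' isocontour"), keeping the band between the outer surface and the found
#' inner boundary.
#'
#' @param skin_removed skin-removed candidate [binary_mask()] from
#'   [remove_skin()].
#' @return An object of class `band_state`: list with `band` (the current
#'   abdominal [binary_mask()]), `dmap` (hull distance map, reused by the
#'   refinement), `d_star`, `hull` and `removed_last_iter`.
#' @export
identify_abdominal_band <- function(skin_removed) {
  px <- as_mask_pixels(skin_removed)
  if (!any(px)) stop("skin-removed mask is empty", call. = FALSE)
  sp <- mask_spacing(skin_removed)
  hull <- convex_hull_region(binary_mask(px, sp))
  dmap <- chebyshev_distance_map(hull, source = "convex hull of candidates")
  d_star <- most_probable_distance(dmap, binary_mask(px, sp),
                                   target = "zero", within = hull)
  band <- px & dmap$pixels >= 1L & dmap$pixels < d_star
  structure(list(band = binary_mask(band, sp), dmap = dmap,
                 d_star = d_star, hull = hull, removed_last_iter = 0L),
            class = "band_state")
}

#' @export
print.band_state <- function(x, ...) {
  cat(sprintf("<band_state> band %d px, d* = %d, removed last iteration %d\n",
              mask_area(x$band), x$d_star, x$removed_last_iter))
  invisible(x)
}

#' Iteratively refine the abdominal band
#'
#' Repeats until no pixel is removed: locate the isocontour of the (fixed)
#' hull distance map holding the most band pixels, take the largest
#' connected dark region (non-candidate pixels of the skin-removed mask)
#' strictly inside it, and remove the band pixels inside and on that
#' region's convex hull.  Removal is clipped to pixels strictly interior to
#' the located isocontour so the outer band contour is never broken.  The
#' band shrinks monotonically, so termination is guaranteed.
#'
#' @param state a `band_state` from [identify_abdominal_band()].
#' @param skin_removed the same skin-removed candidate mask used to build
#'   `state`; its complement defines the dark pixels.
#' @param max_iters safety cap on iterations (default 50, logged if hit).
#' @return The refined abdominal [binary_mask()].
#' @export
refine_abdominal <- function(state, skin_removed, max_iters = 50L) {
  stopifnot(inherits(state, "band_state"))
  sp <- mask_spacing(state$band)
  band <- as_mask_pixels(state$band)
  dark_all <- !as_mask_pixels(skin_removed)
  d <- state$dmap$pixels
  iter <- 0L
  repeat {
    if (iter >= max_iters) {
      warning("abdominal refinement hit the iteration cap (", max_iters, ")")
      break
    }
    iter <- iter + 1L
    if (!any(band)) break
    d1 <- most_probable_distance(state$dmap, binary_mask(band, sp),
                                 target = "one")
    inside <- d > d1
    dark <- dark_all & inside
    if (!any(dark)) break
    lab <- label_components(dark, 8L)
    sizes <- tabulate(lab[lab > 0L])
    region <- lab == which.max(sizes)
    hull <- tryCatch(as_mask_pixels(convex_hull_region(region)),
                     error = function(e) region)   # degenerate: use region
    removal <- hull & inside                       # keep outer contour intact
    removed <- sum(band & removal)
    if (removed == 0L) break
    band <- band & !removal
  }
  binary_mask(band, sp)
}

#' Finalize the abdominal mask
#'
#' Removes the region belonging to the paraspinal muscles from the refined
#' abdominal band, guaranteeing the two classes are disjoint.
#'
#' @param band refined abdominal [binary_mask()].
#' @param paraspinal paraspinal [binary_mask()] of the same shape.
#' @return `band` minus `paraspinal`.
#' @export
finalize_abdominal <- function(band, paraspinal) {
  if (!identical(dim(as_mask_pixels(band)), dim(as_mask_pixels(paraspinal))))
    stop("band and paraspinal shapes differ", call. = FALSE)
  mask_diff(band, paraspinal)
}
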