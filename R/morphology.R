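# Low-level grid morphology shared by every segmentation stage.
#
# Conventions: matrices are indexed [row, col]; foreground components use
# 8-connectivity so thin diagonal muscle bands stay connected, and the
# background complement therefore uses 4-connectivity (the standard dual
# pairing) wherever holes are identified.

# Indices of the valid 8- (or 4-) neighbours of linear indices `idx` in an
# nr x nc grid, concatenated over the chosen offsets.
neighbour_indices <- function(idx, nr, nc, connectivity = 8L) {
  row <- ((idx - 1L) %% nr) + 1L
  offs <- if (connectivity == 8L)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  else
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  n <- nr * nc
  out <- vector("list", length(offs))
  for (i in seq_along(offs)) {
    dr <- offs[[i]][1L]; dc <- offs[[i]][2L]
    ok <- row + dr >= 1L & row + dr <= nr
    cand <- idx[ok] + dr + dc * nr
    out[[i]] <- cand[cand >= 1L & cand <= n]
  }
  unlist(out, use.names = FALSE)
}

# Breadth-first Chebyshev distance: pixels in `seed` carry 0, pixels of
# `grow` get the number of 3x3 dilation steps needed to reach them, which
# equals the L-infinity distance to the nearest seed pixel.
bfs_chebyshev_levels <- function(seed, grow) {
  nr <- nrow(seed); nc <- ncol(seed)
  dist <- matrix(0L, nr, nc)
  visited <- seed | !grow   # never propagate into non-grow, non-seed pixels
  visited[seed] <- TRUE
  frontier <- which(seed)
  level <- 0L
  while (length(frontier)) {
    level <- level + 1L
    cand <- neighbour_indices(frontier, nr, nc, 8L)
    cand <- unique(cand[!visited[cand]])
    cand <- cand[grow[cand]]
    if (!length(cand)) break
    dist[cand] <- level
    visited[cand] <- TRUE
    frontier <- cand
  }
  dist
}

#' Chebyshev distance map of a region
#'
#' For every foreground pixel, the Chebyshev (L-infinity) distance to the
#' nearest background pixel; background pixels carry distance 0.  Discrete
#' L-infinity distance grows in square "rings", so the map equals the number
#' of 3x3 dilations of the background needed to reach a pixel.
#'
#' @param region a [binary_mask()] (or logical matrix) with non-empty
#'   foreground and at least one background pixel.
#' @param source free-text description of the reference boundary.
#' @return An object of class `distance_map`: list with integer matrix
#'   `pixels` and the `source` string.
#' @export
chebyshev_distance_map <- function(region, source = "region boundary") {
  px <- as_mask_pixels(region)
  if (!any(px)) stop("region is empty", call. = FALSE)
  if (all(px)) stop("region has no background pixels to measure from",
                    call. = FALSE)
  structure(list(pixels = bfs_chebyshev_levels(seed = !px, grow = px),
                 source = source),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %d x %d px, max distance %d (from %s)\n",
              nrow(x$pixels), ncol(x$pixels), max(x$pixels), x$source))
  invisible(x)
}

#' Label connected components
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of component labels (0 = background).  Labels are
#'   assigned in first-pixel (column-major) order, so they are deterministic.
#' @export
label_components <- function(mask, connectivity = 8L) {
  px <- as_mask_pixels(mask)
  nr <- nrow(px); nc <- ncol(px); n <- nr * nc
  fg <- which(px)
  lab <- matrix(0L, nr, nc)
  if (!length(fg)) return(lab)
  pos <- integer(n)
  pos[fg] <- seq_along(fg)
  offs <- if (connectivity == 8L)
    list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  else
    list(c(1L, 0L), c(0L, 1L))
  row <- ((fg - 1L) %% nr) + 1L
  e_from <- e_to <- vector("list", length(offs))
  for (i in seq_along(offs)) {
    dr <- offs[[i]][1L]; dc <- offs[[i]][2L]
    ok <- row + dr >= 1L & row + dr <= nr
    src <- fg[ok]
    nb <- src + dr + dc * nr
    keep <- nb >= 1L & nb <= n
    src <- src[keep]; nb <- nb[keep]
    keep <- px[nb]
    e_from[[i]] <- pos[src[keep]]
    e_to[[i]] <- pos[nb[keep]]
  }
  edges <- rbind(unlist(e_from, use.names = FALSE),
                 unlist(e_to, use.names = FALSE))
  g <- igraph::make_graph(edges = as.vector(edges), n = length(fg),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel in order of first appearance so labels are stable
  u <- unique(memb)
  relabel <- integer(max(memb))
  relabel[u] <- seq_along(u)
  lab[fg] <- relabel[memb]
  lab
}

#' Keep the largest connected component
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return A [binary_mask()] holding only the largest component (ties broken
#'   by first-appearing label).
#' @export
largest_component <- function(mask, connectivity = 8L) {
  px <- as_mask_pixels(mask)
  lab <- label_components(px, connectivity)
  if (max(lab) == 0L) stop("mask has no foreground component", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  binary_mask(lab == keep, mask_spacing(mask))
}

#' Fill interior holes of a mask
#'
#' Background regions (4-connected) not reachable from the image border are
#' considered holes and set to foreground.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @return A [binary_mask()] with holes filled.
#' @export
fill_holes <- function(mask) {
  px <- as_mask_pixels(mask)
  bg <- !px
  if (!any(bg)) return(binary_mask(px, mask_spacing(mask)))
  lab <- label_components(bg, connectivity = 4L)
  nr <- nrow(px); nc <- ncol(px)
  border <- unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc]))
  border <- border[border > 0L]
  hole <- bg & !(lab %in% border)
  binary_mask(px | hole, mask_spacing(mask))
}

#' Remove small connected components
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param min_area_px minimum surviving component area in pixels (>= 1).
#' @return A [binary_mask()] in which every component has area
#'   `>= min_area_px`.
#' @export
filter_small <- function(mask, min_area_px = 20L) {
  stopifnot(min_area_px >= 1L)
  px <- as_mask_pixels(mask)
  if (!any(px) || min_area_px == 1L)
    return(binary_mask(px, mask_spacing(mask)))
  lab <- label_components(px, 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_px)
  binary_mask(array(lab %in% keep, dim = dim(px)), mask_spacing(mask))
}

#' Filled convex hull of a mask
#'
#' Computes the planar convex hull of the foreground pixel centres and
#' rasterises its filled interior (boundary pixels included).  The input is
#' always a subset of the output.
#'
#' @param mask a [binary_mask()] or logical matrix with at least 3
#'   non-collinear foreground pixels.
#' @return A [binary_mask()] of the filled hull.
#' @export
convex_hull_region <- function(mask) {
  px <- as_mask_pixels(mask)
  pts <- which(px, arr.ind = TRUE)
  if (nrow(pts) < 3L)
    stop("convex hull needs at least 3 foreground pixels", call. = FALSE)
  r <- as.numeric(pts[, 1L]); c <- as.numeric(pts[, 2L])
  h <- grDevices::chull(c, r)
  if (length(h) < 3L)
    stop("foreground pixels are collinear; hull is degenerate", call. = FALSE)
  hv_r <- r[h]; hv_c <- c[h]
  out <- matrix(FALSE, nrow(px), ncol(px))
  nv <- length(h)
  nxt <- c(seq_len(nv)[-1L], 1L)
  eps <- 1e-9
  for (row in seq(min(hv_r), max(hv_r))) {
    xs <- numeric(0)
    for (i in seq_len(nv)) {
      y1 <- hv_r[i]; y2 <- hv_r[nxt[i]]
      x1 <- hv_c[i]; x2 <- hv_c[nxt[i]]
      if (y1 == y2) {
        if (y1 == row) xs <- c(xs, x1, x2)
      } else if ((y1 - row) * (y2 - row) <= 0) {
        xs <- c(xs, x1 + (row - y1) * (x2 - x1) / (y2 - y1))
      }
    }
    if (length(xs)) {
      lo <- ceiling(min(xs) - eps); hi <- floor(max(xs) + eps)
      if (lo <= hi) out[row, lo:hi] <- TRUE
    }
  }
  out <- out | px   # hull always contains its generating pixels
  binary_mask(out, mask_spacing(mask))
}

# Set helpers used across the pipeline.
mask_and <- function(a, b)
  binary_mask(as_mask_pixels(a) & as_mask_pixels(b), mask_spacing(a))
mask_or <- function(a, b)
  binary_mask(as_mask_pixels(a) | as_mask_pixels(b), mask_spacing(a))
mask_diff <- function(a, b)
  binary_mask(as_mask_pixels(a) & !as_mask_pixels(b), mask_spacing(a))

# One 3x3 (8-neighbour) binary dilation, used for the vertebra overlap rule.
dilate8 <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  out <- px
  idx <- which(px)
  if (!length(idx)) return(out)
  out[neighbour_indices(idx, nr, nc, 8L)] <- TRUE
  out
}
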