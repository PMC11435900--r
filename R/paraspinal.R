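# Paraspinal muscle segmentation: adaptive double thresholding around the
# soft-tissue histogram peak, a bounding box anchored on the vertebra,
# adaptive corner carving, and rule-based component refinement.

#' Fit a Gaussian to the histogram peak
#'
#' Histograms the HU samples in 1-HU bins, locates the dominant soft-tissue
#' mode, and least-squares fits a Gaussian to the bin counts within a window
#' around the peak.  Least squares on bin counts (rather than sample
#' moments) is robust to the fat and air tails of the mixture.
#'
#' @param values numeric vector of HU samples (at least 100 within the
#'   plausible soft-tissue range).
#' @param k multiplier for the threshold band; default 1.5, giving a
#'   two-sided normal coverage of 86.6%.
#' @param range_hu samples outside this range are discarded before
#'   histogramming; default `c(-200, 200)`.
#' @param window_hu half-width (HU) of the fit window around the modal bin;
#'   default 30.
#' @return An object of class `histogram_fit`: list with `mu`, `sigma`,
#'   `k`, `lo = mu - k*sigma`, `hi = mu + k*sigma` and `coverage`
#'   (the implied two-sided normal coverage of the band).
#' @export
fit_peak_gaussian <- function(values, k = 1.5, range_hu = c(-200, 200),
                              window_hu = 30) {
  v <- values[is.finite(values) & values > range_hu[1] & values < range_hu[2]]
  if (length(v) < 100L)
    stop("need at least 100 samples in the soft-tissue range", call. = FALSE)
  centers <- seq(floor(min(v)), ceiling(max(v)))
  counts <- tabulate(findInterval(v, centers - 0.5), nbins = length(centers))
  if (max(counts) <= 2 * stats::median(counts[counts > 0]))
    stop("histogram has no identifiable peak", call. = FALSE)
  mode_i <- which.max(counts)
  win <- abs(centers - centers[mode_i]) <= window_hu
  est <- fit_gaussian_counts(centers[win], counts[win])
  mu <- est[["mu"]]; sigma <- est[["sigma"]]
  structure(list(mu = mu, sigma = sigma, k = k,
                 lo = mu - k * sigma, hi = mu + k * sigma,
                 coverage = 2 * stats::pnorm(k) - 1),
            class = "histogram_fit")
}

# Least-squares Gaussian fit to histogram bin counts; returns c(A, mu, sigma).
fit_gaussian_counts <- function(x, y) {
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
      start = list(A = max(y), mu = x[which.max(y)],
                   sigma = max(1, diff(range(x)) / 6)),
      lower = c(A = 1e-8, mu = min(x), sigma = 0.05),
      upper = c(A = Inf, mu = max(x), sigma = 10 * diff(range(x))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian peak fit failed: ", conditionMessage(e),
                             call. = FALSE))
  est <- stats::coef(fit)
  c(A = unname(est["A"]), mu = unname(est["mu"]),
    sigma = abs(unname(est["sigma"])))
}

#' @export
print.histogram_fit <- function(x, ...) {
  cat(sprintf(paste0("<histogram_fit> mu = %.2f HU, sigma = %.2f HU, ",
                     "band [%.2f, %.2f] (k = %.2g, coverage %.1f%%)\n"),
              x$mu, x$sigma, x$lo, x$hi, x$k, 100 * x$coverage))
  invisible(x)
}

#' Adaptive double thresholding
#'
#' Foreground iff the pixel lies in `body_pixels` and its HU value falls in
#' the fitted band `[mu - k*sigma, mu + k*sigma]`.
#'
#' @param slice a [ct_slice()].
#' @param body_pixels [binary_mask()] restricting the domain (typically the
#'   skin-removed body interior, so skin never re-enters).
#' @param fit a `histogram_fit` from [fit_peak_gaussian()].
#' @return A [binary_mask()].
#' @export
adaptive_threshold <- function(slice, body_pixels, fit) {
  stopifnot(inherits(slice, "ct_slice"), inherits(fit, "histogram_fit"))
  px <- slice$pixels
  binary_mask(as_mask_pixels(body_pixels) & px >= fit$lo & px <= fit$hi,
              slice$spacing)
}

#' Locate the L3 vertebra
#'
#' Largest 8-connected component of bone-range pixels that intersects the
#' posterior-central zone of the body (columns in the middle third of the
#' body width, rows in its posterior half).
#'
#' @param slice a [ct_slice()].
#' @param body body [binary_mask()] from [extract_body()] (defines the
#'   posterior-central zone).
#' @param bone_hu HU threshold for bone; default 150, the upper muscle
#'   threshold, so bone is exactly the supra-muscle class.
#' @return An object of class `vertebra_region`: list with `mask`
#'   ([binary_mask()]), `top_row`, `left_col`, `right_col` and `center_col`
#'   (midpoint of the lateral bounds).
#' @export
locate_vertebra <- function(slice, body, bone_hu = 150) {
  stopifnot(inherits(slice, "ct_slice"))
  bone <- slice$pixels >= bone_hu
  if (!any(bone))
    stop("no bone-range pixels found; paraspinal branch cannot anchor",
         call. = FALSE)
  bpx <- as_mask_pixels(body)
  rows <- range(which(rowSums(bpx) > 0))
  cols <- range(which(colSums(bpx) > 0))
  zone <- matrix(FALSE, nrow(bpx), ncol(bpx))
  third <- (cols[2] - cols[1]) / 3
  post_rows <- ceiling((rows[1] + rows[2]) / 2):rows[2]
  mid_cols <- ceiling(cols[1] + third):floor(cols[2] - third)
  zone[post_rows, mid_cols] <- TRUE
  lab <- label_components(bone, 8L)
  sizes <- tabulate(lab[lab > 0L])
  cand <- sort(unique(lab[lab > 0L & zone]))
  if (!length(cand))
    stop("no bone component intersects the posterior-central zone",
         call. = FALSE)
  pick <- cand[which.max(sizes[cand])]
  vmask <- lab == pick
  vr <- which(rowSums(vmask) > 0)
  vc <- which(colSums(vmask) > 0)
  structure(list(mask = binary_mask(vmask, slice$spacing),
                 top_row = min(vr),
                 left_col = min(vc), right_col = max(vc),
                 center_col = as.integer(round((min(vc) + max(vc)) / 2))),
            class = "vertebra_region")
}

#' @export
print.vertebra_region <- function(x, ...) {
  cat(sprintf("<vertebra_region> %d px, top row %d, cols [%d, %d], center %d\n",
              mask_area(x$mask), x$top_row, x$left_col, x$right_col,
              x$center_col))
  invisible(x)
}

#' Vertebra-anchored paraspinal bounding box
#'
#' Top border is the vertebra's top row; bottom border is the lowest row
#' holding a candidate pixel; left/right borders sit at twice the greater
#' lateral extent of the vertebra from its vertical center line, clipped to
#' the image.
#'
#' @param vertebra a `vertebra_region` from [locate_vertebra()].
#' @param candidates candidate [binary_mask()] (adaptive-threshold output).
#' @return A list with 0-based-free inclusive indices `top_row`,
#'   `bottom_row`, `left_col`, `right_col` (1-based, inclusive).
#' @export
paraspinal_bbox <- function(vertebra, candidates) {
  stopifnot(inherits(vertebra, "vertebra_region"))
  px <- as_mask_pixels(candidates)
  below <- which(rowSums(px) > 0)
  below <- below[below >= vertebra$top_row]
  if (!length(below))
    stop("no candidate pixels at or below the vertebra top", call. = FALSE)
  w <- 2L * max(vertebra$center_col - vertebra$left_col,
                vertebra$right_col - vertebra$center_col)
  list(top_row = vertebra$top_row,
       bottom_row = max(below),
       left_col = max(1L, vertebra$center_col - w),
       right_col = min(ncol(px), vertebra$center_col + w))
}

# Carve the upper-left corner of `sub` (a logical matrix cropped to the
# bounding box) in place, following the two line-marching passes.  `len` is
# the fixed probe length in pixels, `corner_frac` the fraction of the box
# width/height that the probe series spans.
carve_one_corner <- function(sub, len, corner_frac) {
  nr <- nrow(sub); nc <- ncol(sub)
  if (nr < 2L || nc < 2L) return(sub)
  len <- min(len, nr, nc)
  # pass 1: fixed-length vertical probes from the top edge, one per column;
  # where the probe tip is not muscle, sweep a horizontal segment (left
  # border to that column) downward until its endpoint hits muscle.
  for (x in seq_len(max(1L, floor(nc * corner_frac)))) {
    if (sub[len, x]) next
    r <- len
    while (r <= nr && !sub[r, x]) r <- r + 1L
    stop_row <- min(r, nr + 1L) - 1L
    if (stop_row >= 1L) sub[1:stop_row, 1:x] <- FALSE
  }
  # pass 2: fixed-length horizontal probes from the left edge, one per row;
  # where the probe tip is not muscle, sweep a vertical segment (top border
  # to that row) rightward until its endpoint hits muscle.
  for (y in seq_len(max(1L, floor(nr * corner_frac)))) {
    if (sub[y, len]) next
    cc <- len
    while (cc <= nc && !sub[y, cc]) cc <- cc + 1L
    stop_col <- min(cc, nc + 1L) - 1L
    if (stop_col >= 1L) sub[1:y, 1:stop_col] <- FALSE
  }
  sub
}

#' Adaptive corner carving of the paraspinal candidates
#'
#' Generates series of rectangular removal boxes in the upper-left and
#' upper-right corners of the bounding box.  In each corner, fixed-length
#' probe lines are cast at one-pixel steps (the physical pixel size); where
#' a probe tip lands on a non-muscle pixel, a border-anchored segment is
#' swept away from the corner until its endpoint reaches muscle tissue, and
#' the swept rectangle is removed.  Output is always a subset of the input.
#'
#' @param candidates candidate [binary_mask()].
#' @param box bounding box from [paraspinal_bbox()].
#' @param line_length_px fixed probe length in pixels (default 5).
#' @param corner_frac fraction of the box width (vertical probes) and height
#'   (horizontal probes) spanned by each probe series; default 0.25, i.e.
#'   the probes stay within the corner quarter of the box.
#' @return The carved [binary_mask()].
#' @export
carve_corners <- function(candidates, box, line_length_px = 5L,
                          corner_frac = 0.25) {
  stopifnot(line_length_px >= 1L)
  px <- as_mask_pixels(candidates)
  rows <- box$top_row:box$bottom_row
  cols <- box$left_col:box$right_col
  sub <- px[rows, cols, drop = FALSE]
  sub <- carve_one_corner(sub, line_length_px, corner_frac)
  # mirror the columns to treat the upper-right corner with the same code
  sub <- sub[, rev(seq_len(ncol(sub))), drop = FALSE]
  sub <- carve_one_corner(sub, line_length_px, corner_frac)
  sub <- sub[, rev(seq_len(ncol(sub))), drop = FALSE]
  out <- px
  out[rows, cols] <- sub
  binary_mask(out, mask_spacing(candidates))
}

#' Rule-based paraspinal refinement
#'
#' Applies the location and size criteria: removes components whose overlap
#' with the (1-px dilated) vertebra mask exceeds `vertebra_overlap` of their
#' area; removes components within `border_margin_px` of the box's top,
#' left or right borders; removes components below `min_area_px`; fills
#' interior holes.
#'
#' @param mask carved candidate [binary_mask()] (non-zero only inside the
#'   box).
#' @param vertebra a `vertebra_region`.
#' @param box bounding box from [paraspinal_bbox()].
#' @param min_area_px minimum component area (default 20).
#' @param border_margin_px margin defining "near" a border (default 2).
#' @param vertebra_overlap overlap fraction above which a component is
#'   considered to lie on the vertebra (default 0.5).
#' @return The refined paraspinal [binary_mask()]; may be empty (warned).
#' @export
refine_paraspinal <- function(mask, vertebra, box, min_area_px = 20L,
                              border_margin_px = 2L, vertebra_overlap = 0.5) {
  px <- as_mask_pixels(mask)
  lab <- label_components(px, 8L)
  nlab <- max(lab)
  if (nlab > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = nlab)
    vdil <- dilate8(as_mask_pixels(vertebra$mask))
    on_vert <- tabulate(lab[lab > 0L & vdil], nbins = nlab)
    near <- matrix(FALSE, nrow(px), ncol(px))
    m <- border_margin_px
    near[box$top_row:min(nrow(px), box$top_row + m), ] <- TRUE
    near[, box$left_col:min(ncol(px), box$left_col + m)] <- TRUE
    near[, max(1L, box$right_col - m):box$right_col] <- TRUE
    near_border <- tabulate(lab[lab > 0L & near], nbins = nlab)
    drop <- (on_vert / sizes > vertebra_overlap) | (near_border > 0L) |
      (sizes < min_area_px)
    px <- px & !(lab %in% which(drop))
  }
  out <- fill_holes(binary_mask(px, mask_spacing(mask)))
  if (mask_area(out) == 0L)
    warning("paraspinal refinement removed every component")
  out
}
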