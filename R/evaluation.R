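# Evaluation: pixel-overlap metrics (Dice, precision, recall), boundary
# distance metrics (HD95, ASD) in millimetres, majority-vote consensus of
# multiple annotations, and Table-style per-series summaries.

#' Overlap metrics between two masks
#'
#' `DSC = 2|A&B| / (|A|+|B|)`, `precision = |A&B|/|A|`,
#' `recall = |A&B|/|B|`, each in percent.  `A` is the segmented result and
#' `B` the reference.  Both masks empty gives DSC 100% by convention
#' (warned); precision requires `|A| > 0` and recall `|B| > 0`.
#'
#' @param A,B [binary_mask()]s (or logical matrices) of the same shape.
#' @return Named numeric vector `c(dsc, precision, recall)` in percent.
#' @export
overlap_metrics <- function(A, B) {
  a <- as_mask_pixels(A); b <- as_mask_pixels(B)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ", call. = FALSE)
  na <- sum(a); nb <- sum(b); nab <- sum(a & b)
  if (na == 0L && nb == 0L) {
    warning("both masks empty; DSC defined as 100% by convention")
    return(c(dsc = 100, precision = NA_real_, recall = NA_real_))
  }
  if (na == 0L) stop("precision undefined: segmented mask is empty",
                     call. = FALSE)
  if (nb == 0L) stop("recall undefined: reference mask is empty",
                     call. = FALSE)
  c(dsc = 200 * nab / (na + nb),
    precision = 100 * nab / na,
    recall = 100 * nab / nb)
}

#' Boundary point set of a mask
#'
#' Foreground pixels with at least one background 4-neighbour; the image
#' border counts as background.
#'
#' @param mask a non-empty, non-full [binary_mask()].
#' @return Two-column integer matrix of `(row, col)` boundary coordinates.
#' @export
boundary_points <- function(mask) {
  px <- as_mask_pixels(mask)
  if (!any(px)) stop("mask is empty; boundary undefined", call. = FALSE)
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(px & !inner, arr.ind = TRUE)
}

# Directed minimal Euclidean distances (mm) from each point of `p` to the
# set `q`; both are (row, col) matrices, spacing is c(row_mm, col_mm).
directed_min_dists <- function(p, q, spacing) {
  pr <- p[, 1L] * spacing[1L]; pc <- p[, 2L] * spacing[2L]
  qr <- q[, 1L] * spacing[1L]; qc <- q[, 2L] * spacing[2L]
  out <- numeric(nrow(p))
  block <- max(1L, floor(2e7 / nrow(q)))
  for (s in seq(1L, nrow(p), by = block)) {
    e <- min(s + block - 1L, nrow(p))
    d2 <- outer(pr[s:e], qr, "-")^2 + outer(pc[s:e], qc, "-")^2
    out[s:e] <- sqrt(apply(d2, 1L, min))
  }
  out
}

surface_distances <- function(A, B, spacing) {
  pa <- boundary_points(A)
  pb <- boundary_points(B)
  list(ab = directed_min_dists(pa, pb, spacing),
       ba = directed_min_dists(pb, pa, spacing))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The 95th percentile (linear interpolation between order statistics) of
#' the pooled per-point minimal boundary distances from both directions.
#' This is the standard robust variant of the Hausdorff distance; taking
#' the percentile over the two directed maxima alone would reduce to the
#' full Hausdorff distance.  Symmetric in its arguments.
#'
#' @param A,B [binary_mask()]s with non-empty boundaries.
#' @param spacing pixel spacing in mm `c(row_mm, col_mm)`; defaults to the
#'   spacing carried by `A`.
#' @return HD95 in mm.
#' @export
hd95 <- function(A, B, spacing = mask_spacing(A)) {
  d <- surface_distances(A, B, spacing)
  unname(stats::quantile(c(d$ab, d$ba), 0.95, type = 7))
}

#' Average symmetric surface distance (mm)
#'
#' Sum of the directed per-point minimal boundary distances in both
#' directions divided by the total boundary point count.  Symmetric.
#'
#' @inheritParams hd95
#' @return ASD in mm.
#' @export
asd <- function(A, B, spacing = mask_spacing(A)) {
  d <- surface_distances(A, B, spacing)
  (sum(d$ab) + sum(d$ba)) / (length(d$ab) + length(d$ba))
}

#' Majority-vote consensus of aligned annotations
#'
#' Per pixel, the class receiving a strict majority of the votes
#' (`>= floor(k/2) + 1`, i.e. at least 2 of 3 observers); pixels with no
#' majority class fall to background 0.
#'
#' @param masks list of 3 or more aligned [binary_mask()]s or
#'   [label_map()]s.
#' @return A [binary_mask()] if all inputs are binary, otherwise a
#'   [label_map()] with the union of the input legends.
#' @export
majority_vote <- function(masks) {
  if (!is.list(masks) || length(masks) < 3L)
    stop("majority voting needs at least 3 aligned inputs", call. = FALSE)
  binary <- all(vapply(masks, inherits, logical(1), "binary_mask"))
  mats <- lapply(masks, function(m) {
    if (inherits(m, "binary_mask")) array(as.integer(m$pixels), dim(m$pixels))
    else if (inherits(m, "label_map")) m$pixels
    else stop("inputs must be binary_mask or label_map objects", call. = FALSE)
  })
  dims <- lapply(mats, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("input shapes differ", call. = FALSE)
  k <- length(mats)
  need <- k %/% 2L + 1L
  classes <- sort(unique(unlist(lapply(mats, function(m) unique(as.vector(m))))))
  classes <- classes[classes > 0L]
  out <- matrix(0L, dims[[1L]][1L], dims[[1L]][2L])
  for (cl in classes) {
    votes <- Reduce(`+`, lapply(mats, function(m) (m == cl) + 0L))
    out[votes >= need] <- cl   # at most one class can reach a strict majority
  }
  sp <- mask_spacing(masks[[1L]])
  if (binary) binary_mask(out == 1L, sp)
  else {
    legends <- unlist(lapply(masks, function(m)
      if (inherits(m, "label_map")) m$legend else c("1" = "foreground")))
    legends <- legends[!duplicated(names(legends))]
    if (!"0" %in% names(legends)) legends <- c("0" = "background", legends)
    label_map(out, legend = legends, spacing = sp)
  }
}

#' Evaluate one prediction against a reference
#'
#' @param pred an `l3_segmentation` (its `combined` mask is used) or a
#'   [binary_mask()].
#' @param gold reference [binary_mask()].
#' @param spacing pixel spacing in mm; defaults to the spacing of `gold`.
#' @return An object of class `metric_set`: named list with `dsc`,
#'   `precision`, `recall` (percent), `hd95`, `asd` (mm).
#' @export
evaluate_case <- function(pred, gold, spacing = mask_spacing(gold)) {
  if (inherits(pred, "l3_segmentation")) pred <- pred$combined
  ov <- overlap_metrics(pred, gold)
  structure(list(dsc = unname(ov["dsc"]),
                 precision = unname(ov["precision"]),
                 recall = unname(ov["recall"]),
                 hd95 = hd95(pred, gold, spacing),
                 asd = asd(pred, gold, spacing)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "<metric_set> DSC %.1f%%  precision %.1f%%  recall %.1f%%  HD95 %.2f mm  ASD %.2f mm\n",
    x$dsc, x$precision, x$recall, x$hd95, x$asd))
  invisible(x)
}

#' Summarize per-case metrics as mean and SD per series
#'
#' @param cases data frame with a `series` column and one column per metric
#'   (`dsc`, `precision`, `recall`, `hd95`, `asd`), one row per case; or a
#'   list of `metric_set`s plus a `series` vector.
#' @param series optional character vector of series tags (one per case)
#'   when `cases` is a list of `metric_set`s.
#' @return Data frame with columns `metric`, `series`, `mean`, `sd`, `n`;
#'   sample (n-1) SD, `NA` for n = 1; includes a pooled `"summary"` series.
#' @export
summarize_metrics <- function(cases, series = NULL) {
  if (is.list(cases) && !is.data.frame(cases)) {
    stopifnot(all(vapply(cases, inherits, logical(1), "metric_set")))
    if (is.null(series)) series <- rep("all", length(cases))
    cases <- data.frame(series = series,
                        do.call(rbind, lapply(cases, function(m)
                          as.data.frame(unclass(m)))))
  }
  stopifnot(nrow(cases) >= 1L, "series" %in% names(cases))
  metrics <- intersect(c("dsc", "precision", "recall", "hd95", "asd"),
                       names(cases))
  groups <- c(split(cases, cases$series), list(summary = cases))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(metric = m, series = g,
                 mean = mean(df[[m]]),
                 sd = if (nrow(df) > 1L) stats::sd(df[[m]]) else NA_real_,
                 n = nrow(df))
    }))
  }))
  rownames(out) <- NULL
  out
}
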