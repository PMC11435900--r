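# Full segmentation workflow: preprocessing, then the abdominal and
# paraspinal branches (independent, optionally run concurrently), then
# combination into the complete skeletal-muscle mask.

#' Segmentation configuration
#'
#' All tunable parameters of the pipeline with their defaults.  Areas are
#' expressed in pixels at the reference 1.27 mm spacing and rescaled by
#' `(1.27 / spacing)^2` for other spacings, so the physical cut-off is
#' preserved.
#'
#' @param threshold_lo,threshold_hi global muscle HU band (default -29, 150).
#' @param body_air_hu air/tissue threshold for body extraction (default -500).
#' @param min_area_px small-component cut-off at 1.27 mm spacing (default 20,
#'   about 32 mm^2).
#' @param abdominal_max_iters safety cap for the band refinement (default 50).
#' @param paraspinal_k multiplier of the adaptive threshold band
#'   (default 1.5; two-sided normal coverage 86.6%).
#' @param bone_hu bone threshold for vertebra localization (default 150).
#' @param line_len_px fixed probe length for corner carving (default 5).
#' @param corner_frac fraction of the box spanned by each probe series
#'   (default 0.25).
#' @param border_margin_px "near border" margin in the paraspinal
#'   refinement (default 2).
#' @param vertebra_overlap component/vertebra overlap fraction above which a
#'   component is discarded (default 0.5).
#' @param concurrent run the two branches on separate forked processes
#'   (result is identical to sequential execution).
#' @param ... ignored; forces full argument names.
#' @return An object of class `l3_config` (a named list).
#' @export
l3_config <- function(threshold_lo = -29, threshold_hi = 150,
                      body_air_hu = -500, min_area_px = 20L,
                      abdominal_max_iters = 50L, paraspinal_k = 1.5,
                      bone_hu = 150, line_len_px = 5L, corner_frac = 0.25,
                      border_margin_px = 2L, vertebra_overlap = 0.5,
                      concurrent = FALSE, ...) {
  cfg <- list(threshold_lo = threshold_lo, threshold_hi = threshold_hi,
              body_air_hu = body_air_hu, min_area_px = as.integer(min_area_px),
              abdominal_max_iters = as.integer(abdominal_max_iters),
              paraspinal_k = paraspinal_k, bone_hu = bone_hu,
              line_len_px = as.integer(line_len_px),
              corner_frac = corner_frac,
              border_margin_px = as.integer(border_margin_px),
              vertebra_overlap = vertebra_overlap,
              concurrent = isTRUE(concurrent))
  stopifnot(cfg$threshold_lo < cfg$threshold_hi, cfg$min_area_px >= 1L)
  structure(cfg, class = "l3_config")
}

#' @export
print.l3_config <- function(x, ...) {
  cat("<l3_config>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Area cut-off rescaled to the slice's pixel spacing (reference 1.27 mm).
effective_min_area <- function(cfg, spacing) {
  max(1L, as.integer(round(cfg$min_area_px *
                             (1.27 / sqrt(prod(spacing)))^2)))
}

run_abdominal_branch <- function(skin_removed, cfg) {
  state <- identify_abdominal_band(skin_removed)
  refine_abdominal(state, skin_removed, max_iters = cfg$abdominal_max_iters)
}

run_paraspinal_branch <- function(slice, body_interior, skin_removed, cfg,
                                  min_area) {
  fit <- fit_peak_gaussian(slice$pixels[as_mask_pixels(skin_removed)],
                           k = cfg$paraspinal_k)
  cand <- adaptive_threshold(slice, body_interior, fit)
  body <- fill_holes(binary_mask(as_mask_pixels(body_interior),
                                 slice$spacing))
  vert <- locate_vertebra(slice, body, bone_hu = cfg$bone_hu)
  box <- paraspinal_bbox(vert, cand)
  inbox <- matrix(FALSE, nrow(slice$pixels), ncol(slice$pixels))
  inbox[box$top_row:box$bottom_row, box$left_col:box$right_col] <- TRUE
  cand <- filter_small(mask_and(cand, binary_mask(inbox, slice$spacing)),
                       min_area)
  carved <- carve_corners(cand, box, line_length_px = cfg$line_len_px,
                          corner_frac = cfg$corner_frac)
  refine_paraspinal(carved, vert, box, min_area_px = min_area,
                    border_margin_px = cfg$border_margin_px,
                    vertebra_overlap = cfg$vertebra_overlap)
}

#' Segment skeletal muscles in one axial L3 CT slice
#'
#' Runs the full workflow: global thresholding and skin removal, then the
#' abdominal and paraspinal branches, then combination.  The two branches
#' are independent and may run concurrently; the result contract is
#' identical to sequential execution.  A branch that fails (e.g. no
#' vertebra found) degrades gracefully to an empty mask with a warning.
#'
#' @param slice a [ct_slice()].
#' @param config an [l3_config()].
#' @return An object of class `l3_segmentation`: list with `abdominal`,
#'   `paraspinal` and `combined` [binary_mask()]s (`combined` is their
#'   disjoint union), the `config` snapshot and a `step_log` data frame
#'   (step name, pixels in/out, elapsed ms).
#' @export
segment_l3 <- function(slice, config = l3_config()) {
  stopifnot(inherits(slice, "ct_slice"), inherits(config, "l3_config"))
  log_rows <- list()
  tick <- function(name, px_in, px_out, t0) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      step = name, px_in = px_in, px_out = px_out,
      elapsed_ms = round(1000 * (proc.time()[["elapsed"]] - t0), 1))
  }
  min_area <- effective_min_area(config, slice$spacing)

  t0 <- proc.time()[["elapsed"]]
  tmask <- threshold_band(slice, config$threshold_lo, config$threshold_hi)
  tick("global_threshold", length(slice$pixels), mask_area(tmask), t0)

  t0 <- proc.time()[["elapsed"]]
  body <- extract_body(slice, config$body_air_hu)
  tick("extract_body", mask_area(tmask), mask_area(body), t0)

  t0 <- proc.time()[["elapsed"]]
  sr <- remove_skin(body, mask_and(tmask, body), min_area_px = min_area)
  tick("remove_skin", mask_area(tmask), mask_area(sr$mask), t0)

  empty <- binary_mask(matrix(FALSE, nrow(slice$pixels), ncol(slice$pixels)),
                       slice$spacing)
  abd_fun <- function() {
    tryCatch(run_abdominal_branch(sr$mask, config),
             error = function(e) {
               warning("abdominal branch failed: ", conditionMessage(e),
                       call. = FALSE)
               empty
             })
  }
  par_fun <- function() {
    tryCatch(run_paraspinal_branch(slice, sr$body_interior, sr$mask,
                                   config, min_area),
             error = function(e) {
               warning("paraspinal branch failed: ", conditionMessage(e),
                       call. = FALSE)
               empty
             })
  }

  t0 <- proc.time()[["elapsed"]]
  if (config$concurrent && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(list(abd_fun, par_fun), function(f) f(),
                              mc.cores = 2L)
    ok <- vapply(res, inherits, logical(1), "binary_mask")
    if (!all(ok)) {  # fork-level failure: fall back to sequential
      res <- list(abd_fun(), par_fun())
    }
    band <- res[[1L]]; paraspinal <- res[[2L]]
  } else {
    band <- abd_fun()
    paraspinal <- par_fun()
  }
  abdominal <- finalize_abdominal(band, paraspinal)
  tick("branches", mask_area(sr$mask),
       mask_area(abdominal) + mask_area(paraspinal), t0)

  combined <- mask_or(abdominal, paraspinal)
  stopifnot(sum(as_mask_pixels(abdominal) & as_mask_pixels(paraspinal)) == 0L,
            mask_area(combined) ==
              mask_area(abdominal) + mask_area(paraspinal))
  structure(list(abdominal = abdominal, paraspinal = paraspinal,
                 combined = combined, config = config,
                 step_log = do.call(rbind, log_rows)),
            class = "l3_segmentation")
}

#' @export
print.l3_segmentation <- function(x, ...) {
  cat(sprintf("<l3_segmentation> abdominal %d px, paraspinal %d px, combined %d px\n",
              mask_area(x$abdominal), mask_area(x$paraspinal),
              mask_area(x$combined)))
  print(x$step_log, row.names = FALSE)
  invisible(x)
}
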