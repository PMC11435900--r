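# Synthetic axial L3 phantom: parametric-geometric anatomy (elliptical
# body, skin and subcutaneous-fat rings, a thin closed abdominal muscle
# band, a posterior-central vertebra with transverse and spinous processes,
# psoas and erector-spinae pairs, organ blobs, an optional bowel-gas
# pocket) with class-typical HU statistics, optional contrast enhancement
# and additive low-dose Gaussian noise.  Every pixel carries exactly one
# ground-truth class, so each pipeline stage can be scored without patient
# data.

ellipse_px <- function(nr, nc, cr, cc, sr, sc) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - cr) / sr)^2 + ((c - cc) / sc)^2 <= 1
}

rect_px <- function(nr, nc, r1, r2, c1, c2) {
  out <- matrix(FALSE, nr, nc)
  r1 <- max(1L, round(r1)); r2 <- min(nr, round(r2))
  c1 <- max(1L, round(c1)); c2 <- min(nc, round(c2))
  if (r1 <= r2 && c1 <= c2) out[r1:r2, c1:c2] <- TRUE
  out
}

#' Phantom specification
#'
#' Defaults emulate a 512 x 512 low-dose axial slice at 1.27 x 1.27 mm
#' spacing.  Internal anatomy scales with the body semi-axes; the layer
#' thicknesses are absolute pixels.
#'
#' @param shape grid size `c(rows, cols)`.
#' @param spacing pixel spacing in mm.
#' @param body_semiaxes_mm body ellipse semi-axes `c(row_mm, col_mm)`
#'   (anterior-posterior, lateral).
#' @param skin_px,fat_px,band_px thicknesses (pixels) of the skin ring, the
#'   subcutaneous fat ring and the abdominal muscle band.
#' @param noise_hu SD of the additive Gaussian noise (HU) emulating the
#'   low-dose regime.
#' @param enhanced contrast-enhancement flag: shifts organ/vessel blobs by
#'   +40 to +80 HU while muscle/fat/skin/bone move by at most 5 HU.
#' @param seed RNG seed; the phantom is deterministic given the spec.
#' @param with_gas_pocket include a bowel-gas pocket (-900 HU) hugging the
#'   band's inner boundary (exercises the band refinement).
#' @param with_kidney include a muscle-range kidney blob in the upper-left
#'   of the paraspinal bounding box (exercises corner carving).
#' @param with_organs include the remaining organ/vessel blobs.
#' @param tissue_hu named list of `c(mean, sd)` HU per tissue class.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(512L, 512L), spacing = c(1.27, 1.27),
                         body_semiaxes_mm = c(140, 203),
                         skin_px = 2L, fat_px = 8L, band_px = 5L,
                         noise_hu = 0, enhanced = FALSE, seed = 1L,
                         with_gas_pocket = TRUE, with_kidney = TRUE,
                         with_organs = TRUE,
                         tissue_hu = list(air = c(-1000, 5),
                                          skin = c(30, 10),
                                          fat = c(-100, 15),
                                          muscle = c(45, 10),
                                          organ = c(40, 25),
                                          bone = c(700, 150))) {
  stopifnot(length(shape) == 2L, all(shape >= 64L),
            all(spacing > 0), all(body_semiaxes_mm > 0),
            skin_px >= 1L, fat_px >= 1L, band_px >= 1L, noise_hu >= 0)
  ar <- body_semiaxes_mm[1] / spacing[1]
  ac <- body_semiaxes_mm[2] / spacing[2]
  inner <- c(ar, ac) - (skin_px + fat_px + band_px)
  if (any(inner < 12) || any(inner < 0.4 * c(ar, ac)))
    stop("phantom layers do not fit: body too small for the requested ",
         "skin/fat/band thicknesses", call. = FALSE)
  if (any(c(ar, ac) + 4 > shape / 2))
    stop("body ellipse does not fit in the grid with an air margin",
         call. = FALSE)
  mus <- tissue_hu$muscle[1]
  if (mus <= -29 || mus >= 150)
    stop("muscle HU mean must lie inside the global band (-29, 150)",
         call. = FALSE)
  if (tissue_hu$bone[1] <= 150)
    stop("bone HU mean must exceed 150", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 body_semiaxes_mm = body_semiaxes_mm,
                 skin_px = as.integer(skin_px), fat_px = as.integer(fat_px),
                 band_px = as.integer(band_px), noise_hu = noise_hu,
                 enhanced = isTRUE(enhanced), seed = as.integer(seed),
                 with_gas_pocket = isTRUE(with_gas_pocket),
                 with_kidney = isTRUE(with_kidney),
                 with_organs = isTRUE(with_organs),
                 tissue_hu = tissue_hu),
            class = "phantom_spec")
}

#' Generate a synthetic L3 slice with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return A list with `slice` (a [ct_slice()]), `labels` (a [label_map()]
#'   partitioning every pixel into one class) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  cr0 <- nr / 2; cc0 <- nc / 2
  ar <- spec$body_semiaxes_mm[1] / spec$spacing[1]
  ac <- spec$body_semiaxes_mm[2] / spec$spacing[2]
  off <- cumsum(c(spec$skin_px, spec$fat_px, spec$band_px))
  body <- ellipse_px(nr, nc, cr0, cc0, ar, ac)
  skin_in <- ellipse_px(nr, nc, cr0, cc0, ar - off[1], ac - off[1])
  fat_in <- ellipse_px(nr, nc, cr0, cc0, ar - off[2], ac - off[2])
  band_in <- ellipse_px(nr, nc, cr0, cc0, ar - off[3], ac - off[3])

  lab <- matrix(0L, nr, nc)
  lab[body] <- 1L                 # skin ring
  lab[skin_in] <- 2L              # subcutaneous fat ring
  lab[fat_in] <- 3L               # abdominal muscle band
  lab[band_in] <- 2L              # visceral fat interior

  # paraspinal muscles (class 4), clipped to the interior minus a
  # retroperitoneal fat plane that separates them from the wall band
  fat_gap <- max(2, round(0.1 * ar))
  para_zone <- ellipse_px(nr, nc, cr0, cc0, ar - off[3] - fat_gap,
                          ac - off[3] - fat_gap)
  psoas_l <- ellipse_px(nr, nc, cr0 + 0.209 * ar, cc0 - 0.319 * ac,
                        0.118 * ar, 0.0625 * ac)
  psoas_r <- ellipse_px(nr, nc, cr0 + 0.209 * ar, cc0 + 0.319 * ac,
                        0.118 * ar, 0.0625 * ac)
  erector_l <- ellipse_px(nr, nc, cr0 + 0.591 * ar, cc0 - 0.181 * ac,
                          0.173 * ar, 0.144 * ac)
  erector_r <- ellipse_px(nr, nc, cr0 + 0.591 * ar, cc0 + 0.181 * ac,
                          0.173 * ar, 0.144 * ac)
  paraspinal <- (psoas_l | psoas_r | erector_l | erector_r) & para_zone
  lab[paraspinal] <- 4L

  # organ/vessel blobs (class 5), each with its own HU statistics
  blobs <- list()
  if (spec$with_kidney)
    blobs$kidney <- list(px = ellipse_px(nr, nc, cr0 + 0.182 * ar,
                                         cc0 - 0.45 * ac,
                                         0.109 * ar, 0.05 * ac),
                         mean = 35, sd = 10, enhance = TRUE)
  if (spec$with_organs) {
    blobs$bowel <- list(px = ellipse_px(nr, nc, cr0 - 0.236 * ar,
                                        cc0 + 0.275 * ac,
                                        0.164 * ar, 0.125 * ac),
                        mean = 30, sd = 20, enhance = TRUE)
    blobs$aorta <- list(px = ellipse_px(nr, nc, cr0 - 0.036 * ar,
                                        cc0 - 0.0625 * ac,
                                        0.055 * ar, 0.0375 * ac),
                        mean = 45, sd = 8, enhance = TRUE)
  }
  if (spec$with_gas_pocket)
    blobs$gas <- list(px = ellipse_px(nr, nc, cr0 - 0.554 * ar,
                                      cc0 - 0.60 * ac,
                                      0.091 * ar, 0.075 * ac),
                      mean = -900, sd = 30, enhance = FALSE)
  for (b in names(blobs)) {
    blobs[[b]]$px <- blobs[[b]]$px & band_in & lab != 4L
    lab[blobs[[b]]$px] <- 5L
  }

  # vertebra (class 6) painted last so its extent is exact: body +
  # transverse processes + spinous process
  vert <- ellipse_px(nr, nc, cr0 + 0.218 * ar, cc0, 0.182 * ar, 0.1375 * ac) |
    rect_px(nr, nc, cr0 + 0.273 * ar, cr0 + 0.345 * ar,
            cc0 - 0.2625 * ac, cc0 + 0.2625 * ac) |
    rect_px(nr, nc, cr0 + 0.40 * ar, cr0 + 0.564 * ar,
            cc0 - 0.03125 * ac, cc0 + 0.03125 * ac)
  vert <- vert & band_in
  lab[vert] <- 6L

  # HU image: class mean + per-class jitter, blob overrides, noise,
  # then deterministic enhancement shifts
  th <- spec$tissue_hu
  class_hu <- list(`0` = th$air, `1` = th$skin, `2` = th$fat,
                   `3` = th$muscle, `4` = th$muscle, `5` = th$organ,
                   `6` = th$bone)
  hu <- matrix(0, nr, nc)
  for (code in names(class_hu)) {
    idx <- which(lab == as.integer(code))
    if (length(idx))
      hu[idx] <- stats::rnorm(length(idx), class_hu[[code]][1],
                              class_hu[[code]][2])
  }
  for (b in names(blobs)) {
    idx <- which(blobs[[b]]$px)
    if (length(idx))
      hu[idx] <- stats::rnorm(length(idx), blobs[[b]]$mean, blobs[[b]]$sd)
  }
  if (spec$noise_hu > 0)
    hu <- hu + stats::rnorm(length(hu), 0, spec$noise_hu)
  shifts <- stats::runif(length(blobs), 40, 80)   # drawn regardless of flag
  if (spec$enhanced) {
    hu[lab == 1L] <- hu[lab == 1L] + 3
    hu[lab == 2L] <- hu[lab == 2L] + 2
    hu[lab %in% c(3L, 4L)] <- hu[lab %in% c(3L, 4L)] + 3
    hu[lab == 6L] <- hu[lab == 6L] + 5
    for (i in seq_along(blobs)) {
      b <- blobs[[i]]
      if (b$enhance) hu[b$px] <- hu[b$px] + shifts[i]
    }
  }
  note <- sprintf("phantom seed %d noise %g HU%s", spec$seed, spec$noise_hu,
                  if (spec$enhanced) " enhanced" else "")
  list(slice = ct_slice(hu, spacing = spec$spacing, origin_note = note),
       labels = label_map(lab, spacing = spec$spacing),
       spec = spec)
}

#' Ground-truth muscle mask of a phantom
#'
#' @param labels a phantom [label_map()].
#' @return A [binary_mask()] of the abdominal + paraspinal muscle classes.
#' @export
phantom_muscle_mask <- function(labels)
  label_class_mask(labels, c("abdominal_muscle", "paraspinal_muscle"))

#' Reproducible phantom battery
#'
#' Generates `n` phantoms spanning body sizes, band thicknesses, noise
#' levels \{0, 10, 20, 30\} HU and plain/enhanced acquisition in equal
#' counts, with seeds `base_seed + i`.
#'
#' @param n number of phantoms (>= 1).
#' @param base_seed base RNG seed.
#' @param variations optional data frame overriding the built-in grid;
#'   columns among `body_mm_r`, `body_mm_c`, `band_px`, `noise_hu`,
#'   `enhanced`, recycled to length `n`.
#' @param shape grid size passed to every phantom.
#' @return A list of `n` entries, each `list(slice, labels, tag, spec)`
#'   with a unique tag.
#' @export
phantom_suite <- function(n = 20L, base_seed = 100L, variations = NULL,
                          shape = c(512L, 512L)) {
  stopifnot(n >= 1L)
  sizes <- list(c(125, 180), c(140, 203), c(150, 215), c(132, 190),
                c(145, 208))
  grid <- if (is.null(variations)) {
    p <- ceiling(seq_len(n) / 2)
    data.frame(
      body_mm_r = vapply(sizes[(p - 1L) %% 5L + 1L], `[`, numeric(1), 1L),
      body_mm_c = vapply(sizes[(p - 1L) %% 5L + 1L], `[`, numeric(1), 2L),
      band_px = c(4L, 5L, 6L)[(p - 1L) %% 3L + 1L],
      noise_hu = c(0, 10, 20, 30)[(p - 1L) %% 4L + 1L],
      enhanced = seq_len(n) %% 2L == 0L)
  } else {
    as.data.frame(lapply(variations, rep_len, n))
  }
  lapply(seq_len(n), function(i) {
    g <- grid[i, ]
    spec <- phantom_spec(shape = shape,
                         body_semiaxes_mm = c(g$body_mm_r, g$body_mm_c),
                         band_px = g$band_px, noise_hu = g$noise_hu,
                         enhanced = g$enhanced, seed = base_seed + i)
    ph <- generate_phantom(spec)
    ph$tag <- sprintf("p%02d_%s_noise%02g_band%d", i,
                      if (g$enhanced) "ce" else "plain", g$noise_hu,
                      g$band_px)
    ph
  })
}
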