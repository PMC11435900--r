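test_that("Gaussian fit recovers exact analytic bin counts to numerical tolerance", {
  x <- seq(-40, 140)
  y <- 5000 * exp(-(x - 45)^2 / (2 * 10^2))
  est <- l3seg:::fit_gaussian_counts(x, y)
  expect_equal(unname(est["mu"]), 45, tolerance = 1e-6)
  expect_equal(unname(est["sigma"]), 10, tolerance = 1e-6)
})

test_that("histogram peak fit recovers seeded Normal(45, 10) parameters", {
  set.seed(41)
  err_mu <- err_sigma <- numeric(10)
  for (i in 1:10) {
    fit <- fit_peak_gaussian(rnorm(10000, 45, 10))
    err_mu[i] <- fit$mu - 45
    err_sigma[i] <- fit$sigma - 10
    expect_true(fit$mu > 44 && fit$mu < 46)
    expect_true(fit$sigma > 9 && fit$sigma < 11)
    expect_equal(fit$lo, fit$mu - 1.5 * fit$sigma)
    expect_equal(fit$hi, fit$mu + 1.5 * fit$sigma)
  }
  expect_lte(abs(mean(err_mu)), 0.5)
  expect_lte(abs(mean(err_sigma)), 0.5)
})

test_that("the 1.5-sigma band has the analytic two-sided normal coverage", {
  fit <- fit_peak_gaussian(rnorm(5000, 45, 10), k = 1.5)
  expect_equal(fit$coverage, 2 * pnorm(1.5) - 1)
  expect_equal(round(fit$coverage, 4), 0.8664)
  # the coverage actually implied by the fitted band under the fitted normal
  implied <- pnorm((fit$hi - fit$mu) / fit$sigma) -
    pnorm((fit$lo - fit$mu) / fit$sigma)
  expect_equal(implied, fit$coverage, tolerance = 1e-12)
  expect_error(fit_peak_gaussian(runif(5000, -200, 200)), "peak")
  expect_error(fit_peak_gaussian(rnorm(50, 45, 10)), "100 samples")
})

test_that("adaptive thresholding keeps in-band body pixels only", {
  fit <- fit_peak_gaussian(rnorm(5000, 45, 10))
  px <- matrix(c(fit$mu, fit$mu + 2 * fit$sigma, fit$mu, -100), 2, 2)
  body <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  got <- adaptive_threshold(ct_slice(px), binary_mask(body), fit)
  expect_identical(as.vector(got$pixels), c(TRUE, FALSE, FALSE, FALSE))
  # phantom capture: close to the fitted-band coverage (86.6% by design)
  ph <- small_phantom()
  tm <- threshold_band(ph$slice)
  sr <- remove_skin(extract_body(ph$slice),
                    mask_and(tm, extract_body(ph$slice)))
  pfit <- fit_peak_gaussian(ph$slice$pixels[sr$mask$pixels])
  cand <- adaptive_threshold(ph$slice, sr$body_interior, pfit)
  par_g <- label_class_mask(ph$labels, "paraspinal_muscle")
  capture <- sum(cand$pixels & par_g$pixels) / mask_area(par_g)
  # the band can only capture ~86.6% of muscle pixels by construction; the
  # observed fraction must sit close to that analytic coverage
  expect_lte(abs(capture - pfit$coverage), 0.05)
  expect_gte(capture, 0.80)
})

test_that("vertebra localization picks the posterior-central bone component", {
  px <- matrix(-1000, 60, 60)
  px[10:50, 10:50] <- 40                       # body
  px[32:44, 25:35] <- 700                      # vertebra, 143 px
  px[20:23, 45:49] <- 700                      # lateral rib fragment, 20 px
  body <- extract_body(ct_slice(px))
  vert <- locate_vertebra(ct_slice(px), body)
  expect_true(all(vert$mask$pixels[32:44, 25:35]))
  expect_false(any(vert$mask$pixels[20:23, 45:49]))
  expect_equal(vert$top_row, 32L)
  expect_equal(c(vert$left_col, vert$right_col), c(25L, 35L))
  expect_equal(vert$center_col, 30L)
  expect_error(locate_vertebra(ct_slice(matrix(40, 20, 20)),
                               binary_mask(matrix(TRUE, 20, 20))),
               "no bone")
})

test_that("vertebra localization commutes with left-right mirroring", {
  ph <- small_phantom()
  body <- extract_body(ph$slice)
  vert <- locate_vertebra(ph$slice, body)
  nc <- ncol(ph$slice$pixels)
  mirrored <- ct_slice(ph$slice$pixels[, nc:1], ph$slice$spacing)
  vert_m <- locate_vertebra(mirrored, extract_body(mirrored))
  expect_identical(vert_m$mask$pixels, vert$mask$pixels[, nc:1])
  expect_equal(vert_m$left_col, nc + 1L - vert$right_col)
  expect_equal(vert_m$right_col, nc + 1L - vert$left_col)
  expect_lte(abs(vert_m$center_col - (nc + 1L - vert$center_col)), 1L)
})

test_that("bounding box doubles the greater lateral vertebra extent", {
  mkvert <- function(left, right, top = 20L) {
    m <- matrix(FALSE, 200, 200); m[top:40, left:right] <- TRUE
    structure(list(mask = binary_mask(m), top_row = top,
                   left_col = left, right_col = right,
                   center_col = as.integer(round((left + right) / 2))),
              class = "vertebra_region")
  }
  cand <- matrix(FALSE, 200, 200); cand[150, 90:110] <- TRUE
  v <- mkvert(70L, 130L)            # symmetric, 30 px each side
  box <- paraspinal_bbox(v, binary_mask(cand))
  expect_equal(box$left_col, 100L - 60L)
  expect_equal(box$right_col, 100L + 60L)
  expect_equal(box$top_row, 20L)
  expect_equal(box$bottom_row, 150L)
  v <- mkvert(75L, 130L)            # asymmetric: 27/28 -> uses round mid 103
  w <- 2L * max(v$center_col - 75L, 130L - v$center_col)
  box <- paraspinal_bbox(v, binary_mask(cand))
  expect_equal(box$right_col - v$center_col, w)
  # clipping at the image edge
  v <- mkvert(10L, 150L)
  box <- paraspinal_bbox(v, binary_mask(cand))
  expect_equal(box$left_col, 1L)
  expect_equal(box$right_col, 200L)
  # phantom: the box encloses essentially all paraspinal muscle
  ph <- small_phantom()
  tm <- threshold_band(ph$slice)
  body <- extract_body(ph$slice)
  sr <- remove_skin(body, mask_and(tm, body))
  fit <- fit_peak_gaussian(ph$slice$pixels[sr$mask$pixels])
  cand <- adaptive_threshold(ph$slice, sr$body_interior, fit)
  vert <- locate_vertebra(ph$slice, body)
  box <- paraspinal_bbox(vert, cand)
  inbox <- matrix(FALSE, 192, 192)
  inbox[box$top_row:box$bottom_row, box$left_col:box$right_col] <- TRUE
  par_g <- label_class_mask(ph$labels, "paraspinal_muscle")
  expect_gte(sum(par_g$pixels & inbox) / mask_area(par_g), 0.99)
})

test_that("corner carving removes an empty corner pocket exactly", {
  sub <- matrix(TRUE, 12, 12)
  sub[1:4, 1:4] <- FALSE            # empty pocket bounded by muscle
  box <- list(top_row = 1L, bottom_row = 12L, left_col = 1L, right_col = 12L)
  got <- carve_corners(binary_mask(sub), box, line_length_px = 4L,
                       corner_frac = 1 / 3)
  oracle <- march_oracle_upper_left(sub, 4L, ncols_probe = 4L,
                                    nrows_probe = 4L)
  oracle <- oracle[, 12:1]
  oracle <- march_oracle_upper_left(oracle, 4L, 4L, 4L)[, 12:1]
  expect_identical(got$pixels, oracle)
  # with the pocket empty and everything else muscle, exactly the pocket goes
  expected <- matrix(TRUE, 12, 12); expected[1:4, 1:4] <- FALSE
  expect_identical(got$pixels, expected)
  # a full box is untouched
  full <- binary_mask(matrix(TRUE, 12, 12))
  expect_identical(carve_corners(full, box, 4L)$pixels, full$pixels)
})

test_that("corner carving equals the line-march oracle on random boxes", {
  set.seed(42)
  for (i in 1:25) {
    nr <- sample(8:20, 1); nc <- sample(8:20, 1)
    px <- matrix(runif(nr * nc) < 0.6, nr, nc)
    box <- list(top_row = 1L, bottom_row = nr, left_col = 1L, right_col = nc)
    len <- sample(2:5, 1)
    got <- carve_corners(binary_mask(px), box, len, corner_frac = 0.25)
    o <- march_oracle_upper_left(px, min(len, nr, nc),
                                 max(1L, floor(nc * 0.25)),
                                 max(1L, floor(nr * 0.25)))
    o <- o[, nc:1, drop = FALSE]
    o <- march_oracle_upper_left(o, min(len, nr, nc),
                                 max(1L, floor(nc * 0.25)),
                                 max(1L, floor(nr * 0.25)))
    o <- o[, nc:1, drop = FALSE]
    expect_identical(got$pixels, o)
    expect_true(all(!got$pixels | px))          # carving never adds pixels
  }
})

test_that("corner carving clears the kidney blob but retains the paraspinal muscles", {
  ph <- generate_phantom(phantom_spec(seed = 5L))   # study-scale phantom
  tm <- threshold_band(ph$slice)
  body <- extract_body(ph$slice)
  sr <- remove_skin(body, mask_and(tm, body))
  fit <- fit_peak_gaussian(ph$slice$pixels[sr$mask$pixels])
  cand <- adaptive_threshold(ph$slice, sr$body_interior, fit)
  vert <- locate_vertebra(ph$slice, body)
  box <- paraspinal_bbox(vert, cand)
  inbox <- matrix(FALSE, nrow(cand$pixels), ncol(cand$pixels))
  inbox[box$top_row:box$bottom_row, box$left_col:box$right_col] <- TRUE
  cand <- filter_small(binary_mask(cand$pixels & inbox, cand$spacing), 20L)
  carved <- carve_corners(cand, box)
  organ_in_box <- ph$labels$pixels == 5L & inbox
  before <- sum(cand$pixels & organ_in_box)
  expect_gte(before, 20L)                        # the kidney is in play
  expect_gte(1 - sum(carved$pixels & organ_in_box) / before, 0.90)
  par_g <- label_class_mask(ph$labels, "paraspinal_muscle")
  expect_gte(sum(carved$pixels & par_g$pixels) /
               sum(cand$pixels & par_g$pixels), 0.95)
})

test_that("paraspinal refinement enforces the location and size rules", {
  box <- list(top_row = 1L, bottom_row = 40L, left_col = 1L, right_col = 40L)
  vert_px <- matrix(FALSE, 40, 40); vert_px[15:25, 15:25] <- TRUE
  vert <- structure(list(mask = binary_mask(vert_px), top_row = 15L,
                         left_col = 15L, right_col = 25L, center_col = 20L),
                    class = "vertebra_region")
  px <- matrix(FALSE, 40, 40)
  px[16:24, 16:24] <- TRUE          # 100% on the vertebra -> removed
  px[1:6, 30:36] <- TRUE            # touches the top border -> removed
  px[30:36, 1:4] <- TRUE            # touches the left border -> removed
  px[30:32, 30:31] <- TRUE          # 6 px, below min area -> removed
  px[30:38, 10:20] <- TRUE          # genuine component
  px[33:35, 13:16] <- FALSE         # with a hole -> filled
  out <- refine_paraspinal(binary_mask(px), vert, box, min_area_px = 10L)
  expect_true(all(out$pixels[30:38, 10:20]))
  expect_equal(mask_area(out), 9L * 11L)
  # a component with minority vertebra overlap survives
  px2 <- matrix(FALSE, 40, 40); px2[24:38, 18:22] <- TRUE  # ~13% on vertebra
  out2 <- refine_paraspinal(binary_mask(px2), vert, box, min_area_px = 10L)
  expect_identical(out2$pixels, px2)
  expect_warning(
    refine_paraspinal(binary_mask(matrix(FALSE, 40, 40)), vert, box),
    "every component")
})

test_that("the full branch recovers the paraspinal muscles on a noise-free phantom", {
  ph <- generate_phantom(phantom_spec(seed = 44L))
  seg <- segment_l3(ph$slice)
  par_g <- label_class_mask(ph$labels, "paraspinal_muscle")
  expect_gte(overlap_metrics(seg$paraspinal, par_g)["dsc"], 85)
})
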