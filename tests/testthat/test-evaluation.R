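test_that("overlap metrics follow the set-cardinality definitions", {
  a <- matrix(FALSE, 6, 6); b <- matrix(FALSE, 6, 6)
  a[1, 1:2] <- TRUE; b[1, 2:3] <- TRUE          # |A|=2, |B|=2, |A&B|=1
  got <- overlap_metrics(binary_mask(a), binary_mask(b))
  expect_equal(unname(got), c(50, 50, 50))
  a2 <- matrix(FALSE, 6, 6); a2[2, 1:3] <- TRUE
  b2 <- matrix(FALSE, 6, 6); b2[2, 1:6] <- TRUE # A subset of B, half size
  got <- overlap_metrics(binary_mask(a2), binary_mask(b2))
  expect_equal(unname(got), c(200 * 3 / 9, 100, 50))
  expect_equal(unname(overlap_metrics(binary_mask(b2), binary_mask(b2))),
               c(100, 100, 100))
  empty <- binary_mask(matrix(FALSE, 6, 6))
  expect_warning(e <- overlap_metrics(empty, empty), "convention")
  expect_equal(unname(e["dsc"]), 100)
  expect_error(overlap_metrics(empty, binary_mask(b2)), "precision")
  expect_error(overlap_metrics(binary_mask(b2), empty), "recall")
})

test_that("DSC is symmetric and precision/recall swap under argument exchange", {
  set.seed(51)
  for (i in 1:20) {
    p <- random_mask_pair()
    m1 <- overlap_metrics(binary_mask(p$a), binary_mask(p$b))
    m2 <- overlap_metrics(binary_mask(p$b), binary_mask(p$a))
    expect_equal(m1["dsc"], m2["dsc"])
    expect_equal(unname(m1["precision"]), unname(m2["recall"]))
    expect_equal(unname(m1["recall"]), unname(m2["precision"]))
  }
})

test_that("boundary extraction uses 4-neighbour background adjacency", {
  px <- matrix(FALSE, 7, 7); px[3:5, 3:5] <- TRUE
  b <- boundary_points(binary_mask(px))
  expect_equal(nrow(b), 8L)                      # all but the centre
  expect_false(any(b[, 1] == 4 & b[, 2] == 4))
  single <- matrix(FALSE, 5, 5); single[2, 2] <- TRUE
  expect_equal(unname(boundary_points(binary_mask(single))[1, ]), c(2L, 2L))
  line <- matrix(FALSE, 5, 9); line[3, 2:8] <- TRUE
  expect_equal(nrow(boundary_points(binary_mask(line))), 7L)
  # the image border counts as background
  full <- binary_mask(matrix(TRUE, 4, 4))
  expect_equal(nrow(boundary_points(full)), 12L)
  expect_error(boundary_points(binary_mask(matrix(FALSE, 3, 3))), "empty")
})

test_that("HD95 and ASD match hand-computed single-pair distances", {
  a <- matrix(FALSE, 9, 9); b <- matrix(FALSE, 9, 9)
  a[5, 2] <- TRUE; b[5, 5] <- TRUE               # 3 columns apart
  sp <- c(1.27, 1.27)
  expect_equal(hd95(binary_mask(a, sp), binary_mask(b, sp)), 3 * 1.27)
  a2 <- matrix(FALSE, 9, 9); b2 <- matrix(FALSE, 9, 9)
  a2[3, 4] <- TRUE; b2[5, 4] <- TRUE             # 2 rows apart
  expect_equal(asd(binary_mask(a2, sp), binary_mask(b2, sp)), 2 * 1.27)
  m <- binary_mask(a, sp)
  expect_equal(hd95(m, m), 0)
  expect_equal(asd(m, m), 0)
})

test_that("boundary metrics equal brute-force oracles, are symmetric and translation-invariant", {
  set.seed(52)
  sp <- c(1.27, 1.27)
  for (i in 1:50) {
    p <- random_mask_pair()
    A <- binary_mask(p$a, sp); B <- binary_mask(p$b, sp)
    expect_equal(hd95(A, B), brute_hd95(p$a, p$b, sp), tolerance = 1e-9)
    expect_equal(asd(A, B), brute_asd(p$a, p$b, sp), tolerance = 1e-9)
    expect_equal(hd95(A, B), hd95(B, A), tolerance = 1e-12)
    expect_equal(asd(A, B), asd(B, A), tolerance = 1e-12)
  }
  # anisotropic spacing is honoured
  a <- matrix(FALSE, 6, 6); b <- matrix(FALSE, 6, 6)
  a[2, 2] <- TRUE; b[4, 5] <- TRUE
  expect_equal(hd95(binary_mask(a, c(2, 0.5)), binary_mask(b, c(2, 0.5))),
               sqrt((2 * 2)^2 + (3 * 0.5)^2))
  # translating both masks together changes nothing
  p <- random_mask_pair(12L)
  big_a <- matrix(FALSE, 40, 40); big_b <- matrix(FALSE, 40, 40)
  big_a[3:(2 + nrow(p$a)), 3:(2 + ncol(p$a))] <- p$a
  big_b[3:(2 + nrow(p$b)), 3:(2 + ncol(p$b))] <- p$b
  sh_a <- matrix(FALSE, 40, 40); sh_b <- matrix(FALSE, 40, 40)
  sh_a[13:(12 + nrow(p$a)), 9:(8 + ncol(p$a))] <- p$a
  sh_b[13:(12 + nrow(p$b)), 9:(8 + ncol(p$b))] <- p$b
  expect_equal(hd95(binary_mask(big_a, sp), binary_mask(big_b, sp)),
               hd95(binary_mask(sh_a, sp), binary_mask(sh_b, sp)))
  expect_equal(asd(binary_mask(big_a, sp), binary_mask(big_b, sp)),
               asd(binary_mask(sh_a, sp), binary_mask(sh_b, sp)))
})

test_that("majority voting implements the at-least-two-observers rule", {
  a <- binary_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  b <- binary_mask(matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  c3 <- binary_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  got <- majority_vote(list(a, b, c3))
  expect_identical(as.vector(got$pixels), c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(majority_vote(list(a, a, a))$pixels, a$pixels)
  # permutation invariance
  expect_identical(majority_vote(list(c3, a, b))$pixels, got$pixels)
  # multi-class with no majority falls to background
  l1 <- label_map(matrix(1L, 2, 2)); l2 <- label_map(matrix(2L, 2, 2))
  l0 <- label_map(matrix(0L, 2, 2))
  expect_identical(unique(as.vector(majority_vote(list(l1, l2, l0))$pixels)),
                   0L)
  expect_error(majority_vote(list(a, b)), "at least 3")
  expect_error(majority_vote(list(a, b, binary_mask(matrix(TRUE, 3, 3)))),
               "shapes")
})

test_that("majority voting equals the per-pixel vote-count oracle on 8x8 stacks", {
  set.seed(53)
  for (i in 1:40) {
    k <- sample(3:5, 1)
    stack <- lapply(seq_len(k), function(j)
      label_map(matrix(sample(0:3, 64, TRUE), 8, 8)))
    got <- majority_vote(stack)$pixels
    oracle <- matrix(0L, 8, 8)
    need <- k %/% 2 + 1
    for (r in 1:8) for (c in 1:8) {
      votes <- table(vapply(stack, function(s) s$pixels[r, c], integer(1)))
      votes <- votes[names(votes) != "0"]
      win <- votes[votes >= need]
      if (length(win) == 1L) oracle[r, c] <- as.integer(names(win))
    }
    expect_identical(got, oracle)
  }
})

test_that("case evaluation and summaries reproduce hand computations", {
  px <- matrix(FALSE, 20, 20); px[5:15, 5:15] <- TRUE
  gold <- binary_mask(px)
  expect_equal(unclass(evaluate_case(gold, gold))[1:5],
               list(dsc = 100, precision = 100, recall = 100,
                    hd95 = 0, asd = 0))
  eroded <- px; eroded[5, ] <- FALSE             # prediction misses one row
  m <- evaluate_case(binary_mask(eroded), gold)
  expect_equal(m$precision, 100)
  expect_lt(m$recall, 100)
  cases <- data.frame(series = c("plain", "ce"), dsc = c(90, 94),
                      hd95 = c(4, 6))
  s <- summarize_metrics(cases)
  pooled <- s[s$series == "summary" & s$metric == "dsc", ]
  expect_equal(pooled$mean, 92)
  expect_equal(pooled$sd, sqrt(8))               # sample SD of {90, 94}
  expect_equal(s[s$series == "plain" & s$metric == "dsc", "n"], 1L)
  expect_true(is.na(s[s$series == "plain" & s$metric == "dsc", "sd"]))
  # permutation invariance of the summary
  s2 <- summarize_metrics(cases[2:1, ])
  expect_equal(s[order(s$metric, s$series), c("mean", "sd")],
               s2[order(s2$metric, s2$series), c("mean", "sd")],
               ignore_attr = TRUE)
})
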