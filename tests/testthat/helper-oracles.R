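# Independent brute-force oracles and shared fixtures.  The oracles are
# deliberately naive (all-pairs minimisation, per-level counting, half-plane
# hull membership) so they share no code with the implementation they check.

random_mask <- function(nr, nc, p = 0.4, spacing = c(1.27, 1.27)) {
  binary_mask(matrix(stats::runif(nr * nc) < p, nr, nc), spacing)
}

# All-pairs Chebyshev distance of each foreground pixel to the nearest
# background pixel (O(n^2)).
brute_chebyshev <- function(px) {
  bg <- which(!px, arr.ind = TRUE)
  out <- matrix(0L, nrow(px), ncol(px))
  fg <- which(px, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1L], fg[i, 2L]] <-
      min(pmax(abs(bg[, 1L] - fg[i, 1L]), abs(bg[, 2L] - fg[i, 2L])))
  }
  out
}

# Per-level counting oracle for the most probable distance.
brute_most_probable <- function(dmat, ind, target_one = FALSE,
                                within = NULL) {
  match_px <- if (target_one) ind else !ind
  keep <- dmat >= 1L
  if (!is.null(within)) keep <- keep & within
  levels <- seq_len(max(dmat))
  counts <- vapply(levels, function(d) sum(dmat == d & keep & match_px),
                   integer(1))
  levels[which.max(counts)]
}

# Directed minimal Euclidean distances via plain outer products.
brute_directed <- function(p, q, spacing) {
  d <- sqrt(outer(p[, 1L] * spacing[1L], q[, 1L] * spacing[1L], "-")^2 +
              outer(p[, 2L] * spacing[2L], q[, 2L] * spacing[2L], "-")^2)
  apply(d, 1L, min)
}

brute_boundary <- function(px) {
  pts <- which(px, arr.ind = TRUE)
  keep <- logical(nrow(pts))
  nr <- nrow(px); nc <- ncol(px)
  for (i in seq_len(nrow(pts))) {
    r <- pts[i, 1L]; c <- pts[i, 2L]
    nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    for (j in 1:4) {
      rr <- nb[j, 1L]; cc <- nb[j, 2L]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc || !px[rr, cc]) {
        keep[i] <- TRUE
        break
      }
    }
  }
  pts[keep, , drop = FALSE]
}

brute_hd95 <- function(pxa, pxb, spacing) {
  pa <- brute_boundary(pxa); pb <- brute_boundary(pxb)
  pooled <- c(brute_directed(pa, pb, spacing),
              brute_directed(pb, pa, spacing))
  unname(stats::quantile(pooled, 0.95, type = 7))
}

brute_asd <- function(pxa, pxb, spacing) {
  pa <- brute_boundary(pxa); pb <- brute_boundary(pxb)
  dab <- brute_directed(pa, pb, spacing)
  dba <- brute_directed(pb, pa, spacing)
  (sum(dab) + sum(dba)) / (length(dab) + length(dba))
}

# A random mask pair guaranteed to have non-empty, non-full masks.
random_mask_pair <- function(max_side = 20L) {
  repeat {
    nr <- sample(5:max_side, 1L); nc <- sample(5:max_side, 1L)
    a <- matrix(stats::runif(nr * nc) < 0.35, nr, nc)
    b <- matrix(stats::runif(nr * nc) < 0.35, nr, nc)
    if (any(a) && any(b) && !all(a) && !all(b)) return(list(a = a, b = b))
  }
}

# Gift-wrapping convex hull membership: pixel centre is in the hull iff it
# lies on the inner side of every hull edge.
brute_hull_member <- function(pts, r, c, eps = 1e-9) {
  h <- grDevices::chull(pts[, 2L], pts[, 1L])   # (x = col, y = row)
  hx <- pts[h, 2L]; hy <- pts[h, 1L]
  nv <- length(h)
  # chull returns vertices clockwise in standard orientation; normalise by
  # checking the signed area and flipping if needed
  area <- sum(hx * hy[c(2:nv, 1L)] - hx[c(2:nv, 1L)] * hy)
  if (area < 0) { hx <- rev(hx); hy <- rev(hy) }
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (r - hy[i]) - (hy[j] - hy[i]) * (c - hx[i])
    if (cross < -eps) return(FALSE)
  }
  TRUE
}

# Small phantom used throughout the unit tests (fast: ~0.1 s to segment).
small_phantom <- function(seed = 3L, ...) {
  generate_phantom(phantom_spec(shape = c(192L, 192L),
                                body_semiaxes_mm = c(55, 75),
                                seed = seed, ...))
}

# Step-by-step simulation of the corner line-marching rules for one
# upper-left corner (independent re-derivation used against carve_corners).
march_oracle_upper_left <- function(sub, len, ncols_probe, nrows_probe) {
  nr <- nrow(sub); nc <- ncol(sub)
  for (x in seq_len(ncols_probe)) {
    if (!sub[len, x]) {
      r <- len
      while (r <= nr && !sub[r, x]) r <- r + 1L
      if (r - 1L >= 1L) sub[1:(r - 1L), 1:x] <- FALSE
    }
  }
  for (y in seq_len(nrows_probe)) {
    if (!sub[y, len]) {
      cc <- len
      while (cc <= nc && !sub[y, cc]) cc <- cc + 1L
      if (cc - 1L >= 1L) sub[1:y, 1:(cc - 1L)] <- FALSE
    }
  }
  sub
}
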