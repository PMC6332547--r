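# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

# Euclidean dilation by per-voxel nearest-distance scan: a voxel is set iff
# its center lies within `margin` mm of the center of some input voxel.
oracle_dilate <- function(vox, spacing, margin) {
  dims <- dim(vox)
  idx_all <- which(array(TRUE, dims), arr.ind = TRUE)
  xyz <- sweep(idx_all - 0.5, 2, spacing, `*`)
  idx_in <- which(vox, arr.ind = TRUE)
  pts <- sweep(idx_in - 0.5, 2, spacing, `*`)
  mind2 <- rep(Inf, nrow(xyz))
  for (r in seq_len(nrow(pts))) {
    d2 <- (xyz[, 1] - pts[r, 1])^2 + (xyz[, 2] - pts[r, 2])^2 +
      (xyz[, 3] - pts[r, 3])^2
    mind2 <- pmin(mind2, d2)
  }
  array(mind2 <= margin^2 + 1e-9, dims)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mwu_exact <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(sel) sum(r[sel]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  sels <- utils::combn(n_a + n_b, n_a)
  us <- apply(sels, 2, u_of)
  p <- 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9))
  min(p, 1)
}

# AUC by O(n^2) pair counting with half credit for ties
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) tot <- tot + sum(x > neg) + 0.5 * sum(x == neg)
  tot / (length(pos) * length(neg))
}

# two-point probit solve by bisection on TD50 (independent of the package's
# closed form): given NTCP(d1)=p1, each candidate TD50 determines
# m = (d1 - TD50) / (qnorm(p1) * TD50); bisect on the residual at (d2, p2)
oracle_two_point_lyman <- function(d1, p1, d2, p2) {
  resid <- function(td50) {
    m <- (d1 - td50) / (qnorm(p1) * td50)
    pnorm((d2 - td50) / (m * td50)) - p2
  }
  td50 <- uniroot(resid, c(max(d1, d2) + 1e-6, 500), tol = 1e-12)$root
  m <- (d1 - td50) / (qnorm(p1) * td50)
  c(td50 = td50, m = m)
}

# small random blob-ish mask for geometry property tests
random_mask <- function(dims, n_seeds, spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  vox <- array(FALSE, dims)
  for (s in seq_len(n_seeds)) {
    c0 <- sapply(dims, function(d) sample(seq(2, d - 1), 1))
    vox[c0[1], c0[2], c0[3]] <- TRUE
  }
  structure_mask("RANDOM", vox, spacing)
}
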