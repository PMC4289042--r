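# Independent brute-force oracles used to validate the fast implementations.

# Box count by explicit triple loop over lattice cells anchored at the
# foreground bounding-box minimum corner.
oracle_box_count <- function(grid, r) {
  idx <- which(grid, arr.ind = TRUE)
  mins <- apply(idx, 2, min)
  maxs <- apply(idx, 2, max)
  d <- dim(grid)
  cnt <- 0L
  for (cx in seq(mins[1], maxs[1], by = r)) {
    for (cy in seq(mins[2], maxs[2], by = r)) {
      for (cz in seq(mins[3], maxs[3], by = r)) {
        sub <- grid[cx:min(cx + r - 1, d[1]),
                    cy:min(cy + r - 1, d[2]),
                    cz:min(cz + r - 1, d[3])]
        if (any(sub)) cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# Dilated voxel count as the union of explicit ball offsets around every
# foreground voxel (equivalently: voxels whose min distance to the
# foreground is <= r), independent of the distance-transform path.
oracle_dilate_count <- function(grid, r) {
  d <- dim(grid)
  pad <- r
  big <- array(FALSE, d + 2L * pad)
  off <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  off <- off[off$x^2 + off$y^2 + off$z^2 <= r^2, , drop = FALSE]
  fg <- which(grid, arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    ix <- cbind(fg[, 1] + pad + off$x[k],
                fg[, 2] + pad + off$y[k],
                fg[, 3] + pad + off$z[k])
    big[ix] <- TRUE
  }
  sum(big)
}

# Literal minimum-distance check on tiny grids.
oracle_dilate_count_mindist <- function(grid, r) {
  d <- dim(grid)
  fg <- which(grid, arr.ind = TRUE)
  cand <- as.matrix(expand.grid((1 - r):(d[1] + r),
                                (1 - r):(d[2] + r),
                                (1 - r):(d[3] + r)))
  cnt <- 0L
  for (i in seq_len(nrow(cand))) {
    d2 <- (fg[, 1] - cand[i, 1])^2 + (fg[, 2] - cand[i, 2])^2 +
      (fg[, 3] - cand[i, 3])^2
    if (min(d2) <= r^2) cnt <- cnt + 1L
  }
  cnt
}

# Exact two-tailed Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  rk <- rank(pooled)
  u1_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  u1_all <- apply(combs, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  lo <- mean(u1_all <= u1_obs)
  hi <- mean(u1_all >= u1_obs)
  min(1, 2 * min(lo, hi))
}

# Menger sponge membership by direct recursion (not the digit test).
oracle_menger_grid <- function(level) {
  if (level == 0) return(array(TRUE, c(1, 1, 1)))
  sub <- oracle_menger_grid(level - 1)
  n <- 3L^(level - 1L)
  out <- array(FALSE, c(3L * n, 3L * n, 3L * n))
  for (i in 0:2) for (j in 0:2) for (k in 0:2) {
    if (sum(c(i, j, k) == 1) >= 2) next
    out[i * n + 1:n, j * n + 1:n, k * n + 1:n] <- sub
  }
  out
}

random_mask <- function(max_edge, p = 0.2, min_fg = 1) {
  repeat {
    d <- sample(3:max_edge, 3, replace = TRUE)
    g <- array(stats::runif(prod(d)) < p, d)
    if (sum(g) >= min_fg) return(binary_mask(g))
  }
}
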