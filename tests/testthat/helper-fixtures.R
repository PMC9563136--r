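# Shared fixtures: all built in code, small grids for speed.

# Minimal phantom satisfying the structure-set invariants (40^3 at 2.5 mm is
# the smallest supported grid).
small_phantom <- function(seed = 7, shape = c(44, 44, 44)) {
  generate_phantom(shape, 2.5, seed = seed)
}

# A dose grid with explicit voxel values in a given mask and zero elsewhere.
dose_with_values <- function(mask, values_in_mask, background = 0) {
  stopifnot(sum(mask) == length(values_in_mask))
  a <- array(background, dim(mask))
  a[mask] <- values_in_mask
  a
}

# A rectangular mask in an otherwise empty grid.
box_mask <- function(shape, from, to) {
  m <- array(FALSE, shape)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}

# Independent Dx oracle: descending sort, element ceil(x/100 * N).
oracle_dx <- function(doses, x) {
  s <- sort(doses, decreasing = TRUE)
  s[ceiling(x / 100 * length(s))]
}

# Independent Vx oracle: inclusive counting.
oracle_vx <- function(doses, thr) 100 * sum(doses >= thr) / length(doses)

# Exhaustive Euclidean-ball dilation oracle: a voxel is in the expansion iff
# some in-mask voxel center lies within `margin` mm of its center.
oracle_expand <- function(mask, margin, spacing) {
  spacing <- rep_len(spacing, 3L)
  idx <- which(mask, arr.ind = TRUE)
  pos <- t(t(idx - 1) * spacing)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(prod(dim(mask)))) {
    p <- (arrayInd(i, dim(mask)) - 1) * spacing
    d2 <- colSums((t(pos) - as.numeric(p))^2)
    out[i] <- min(d2) <= margin^2 + 1e-9
  }
  out
}

# Exact Wilcoxon signed-rank test by enumerating all 2^n sign assignments of
# the absolute differences (two-sided, requires no ties and no zeros).
# Returns the V statistic and the two-sided p-value.
oracle_wilcoxon_exact <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  m <- sum(r)
  p <- if (v_obs > m / 2) 2 * mean(v_all >= v_obs) else 2 * mean(v_all <= v_obs)
  list(statistic = v_obs, p_value = min(1, p))
}
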