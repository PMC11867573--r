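# Independent brute-force oracles, deliberately sharing no code with the
# package internals.

# pure-R double loop: nearest-neighbour distance from each row of X to Y
oracle_nn_dists <- function(X, Y) {
  vapply(seq_len(nrow(X)), function(i) {
    sqrt(min(colSums((t(Y) - X[i, ])^2)))
  }, numeric(1))
}

oracle_directed_hd <- function(X, Y) max(oracle_nn_dists(X, Y))

# q-th percentile with linear interpolation between order statistics
oracle_percentile <- function(v, q) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# ICC(2,1) via R's ANOVA machinery (independent route from the package's
# explicit mean-square formulas)
oracle_icc_aov <- function(m) {
  df <- data.frame(
    value = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(value ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# exact two-sided rank-sum p by enumerating every assignment of ranks
oracle_wilcox_exact_p <- function(x, y) {
  n <- length(x)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n)])
  # pooled tie-free ranks are 1..N, so each assignment's rank sum is the
  # sum of the chosen rank indices
  all_w <- colSums(utils::combn(length(ranks), n))
  p_le <- mean(all_w <= w_obs)
  p_ge <- mean(all_w >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# random small binary mask guaranteed non-empty
random_mask <- function(dim = c(8, 8, 6), p = 0.4, spacing = c(1, 1, 3)) {
  repeat {
    a <- array(as.integer(stats::runif(prod(dim)) < p), dim)
    if (any(a == 1L)) break
  }
  label_volume(a, spacing = spacing)
}

# rasterize a sphere: voxel centres within radius r of center (world mm)
sphere_mask <- function(center, r, spacing, grid_shape) {
  ax <- function(i) (seq_len(grid_shape[i]) - 0.5) * spacing[i]
  x <- ax(1); y <- ax(2); z <- ax(3)
  inside <- outer(outer((x - center[1])^2, (y - center[2])^2, `+`),
                  (z - center[3])^2, `+`) <= r^2
  label_volume(array(as.integer(inside), grid_shape), spacing = spacing)
}

# compact phantom geometry for fast pipeline tests (world 96 x 96 x 96 mm)
small_phantom_params <- function(...) {
  phantom_params(
    grid_shape = c(48L, 48L, 24L), spacing = c(2, 2, 4),
    bladder_semiaxes = c(15, 13, 12), bladder_center = c(48, 26, 60),
    rectum_radius = 8, rectum_z = c(44, 84), rectum_center_xy = c(48, 66),
    rectum_curve = 2, anal_radius = 6, anal_z = c(16, 36),
    femoral_radius = 10,
    femoral_centers = rbind(c(16, 50, 56), c(80, 50, 56)),
    ...
  )
}
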