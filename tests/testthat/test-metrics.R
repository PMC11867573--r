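test_that("dsc matches hand-computed overlaps and its limits", {
  cube <- array(0L, c(6, 6, 6))
  cube[2:3, 2:3, 2:3] <- 1L
  a <- label_volume(cube)
  expect_identical(dsc(a, a), 1)

  other <- array(0L, c(6, 6, 6))
  other[5:6, 5:6, 5:6] <- 1L
  b <- label_volume(other)
  expect_identical(dsc(a, b), 0)

  half <- array(0L, c(6, 6, 6))
  half[2:3, 2:3, 3:4] <- 1L   # |A| = 8, |B| = 8, |A n B| = 4
  expect_equal(dsc(a, label_volume(half)), 0.5)

  empty <- label_volume(array(0L, c(6, 6, 6)))
  expect_equal(dsc(a, empty), 0)
  expect_error(dsc(empty, empty), "undefined")
  expect_error(dsc(a, label_volume(array(0L, c(5, 6, 6)))), "grid_shape")
})

test_that("directed/undirected HD match simple geometry and expose asymmetry", {
  expect_equal(directed_hd(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 5)
  X <- rbind(c(0, 0, 0), c(1, 2, 3))
  Y <- rbind(X, c(9, 9, 9))
  expect_equal(directed_hd(X, Y), 0)   # X subset of Y
  A <- rbind(c(0, 0, 0), c(10, 0, 0))
  B <- rbind(c(0, 0, 0))
  expect_equal(directed_hd(A, B), 10)
  expect_equal(directed_hd(B, A), 0)
  expect_equal(undirected_hd(A, B), 10)
  expect_equal(undirected_hd(B, A), 10)
  expect_equal(undirected_hd(X, X), 0)
  expect_error(directed_hd(A[0, , drop = FALSE], B), "empty")
})

test_that("percentile HD follows the linear-interpolation order-statistic rule", {
  # constant nearest-distance multiset: any percentile returns the constant
  X <- cbind(seq(0, 9), 0, 0)
  Y <- X
  Y[, 2] <- 2.5
  for (q in c(10, 50, 95, 100)) {
    expect_equal(directed_percentile_hd(X, Y, q), 2.5)
  }
  # q = 100 reduces to the directed HD
  A <- rbind(c(0, 0, 0), c(10, 0, 0))
  B <- rbind(c(0, 0, 0))
  expect_equal(directed_percentile_hd(A, B, 100), directed_hd(A, B))

  # 99 distances of 1 and one of 50: compare against the sort-and-
  # interpolate oracle
  set.seed(7)
  X <- cbind(runif(100, 0, 50), runif(100, 0, 50), runif(100, 0, 50))
  Y <- X
  Y[, 3] <- Y[, 3] + 1
  Y[100, ] <- X[100, ] + c(0, 0, 50)
  d <- oracle_nn_dists(X, Y)
  expect_equal(directed_percentile_hd(X, Y, 95), oracle_percentile(d, 95))

  expect_error(directed_percentile_hd(X, Y, 0), "percentile")
  expect_error(directed_percentile_hd(X, Y, 101), "percentile")
})

test_that("point-set metrics equal the brute-force double-loop oracle", {
  set.seed(21)
  for (i in 1:30) {
    a <- random_mask(p = runif(1, 0.2, 0.6))
    b <- random_mask(p = runif(1, 0.2, 0.6))
    X <- boundary_points(a)
    Y <- boundary_points(b)
    expect_equal(directed_hd(X, Y), oracle_directed_hd(X, Y), tolerance = 1e-9)
    expect_equal(undirected_hd(X, Y),
                 max(oracle_directed_hd(X, Y), oracle_directed_hd(Y, X)),
                 tolerance = 1e-9)
    q <- runif(1, 1, 100)
    expect_equal(directed_percentile_hd(X, Y, q),
                 oracle_percentile(oracle_nn_dists(X, Y), q),
                 tolerance = 1e-9)
  }
})

test_that("grid-path hd95/hd_max equal the point-set brute force on shared grids", {
  set.seed(31)
  for (i in 1:15) {
    a <- random_mask(p = 0.4)
    b <- random_mask(p = 0.4)
    X <- boundary_points(a)
    Y <- boundary_points(b)
    q <- sample(c(50, 95, 100), 1)
    expect_equal(
      hd95(a, b, q = q),
      (oracle_percentile(oracle_nn_dists(X, Y), q) +
         oracle_percentile(oracle_nn_dists(Y, X), q)) / 2,
      tolerance = 1e-9
    )
    expect_equal(hd_max(a, b),
                 max(oracle_directed_hd(X, Y), oracle_directed_hd(Y, X)),
                 tolerance = 1e-9)
  }
})

test_that("hd95 is symmetric, bounded by the maximum HD, and zero on identity", {
  set.seed(41)
  cube <- random_mask(p = 0.5)
  expect_equal(hd95(cube, cube), 0)
  for (i in 1:25) {
    a <- random_mask(p = 0.4)
    b <- random_mask(p = 0.4)
    expect_equal(hd95(a, b), hd95(b, a), tolerance = 1e-12)
    expect_equal(dsc(a, b), dsc(b, a))
    expect_lte(hd95(a, b), hd_max(a, b) + 1e-12)
  }
})

test_that("translating a solid cube moves hd95 by exactly the shift", {
  for (t_vox in c(1L, 2L)) {
    big <- array(0L, c(20, 14, 14))
    big[3:12, 3:12, 3:12] <- 1L
    sh <- array(0L, c(20, 14, 14))
    sh[(3 + t_vox):(12 + t_vox), 3:12, 3:12] <- 1L
    a <- label_volume(big)
    b <- label_volume(sh)
    X <- boundary_points(a)
    Y <- boundary_points(b)
    oracle <- (oracle_percentile(oracle_nn_dists(X, Y), 95) +
                 oracle_percentile(oracle_nn_dists(Y, X), 95)) / 2
    expect_equal(hd95(a, b), oracle, tolerance = 1e-9)
    expect_equal(hd95(a, b), t_vox)
  }
})

test_that("HD scales with spacing while DSC is scale-invariant", {
  set.seed(51)
  a <- random_mask(spacing = c(1, 1, 3))
  b <- random_mask(spacing = c(1, 1, 3))
  s <- 2.5
  a2 <- label_volume(a$voxels, spacing = s * a$spacing)
  b2 <- label_volume(b$voxels, spacing = s * b$spacing)
  expect_equal(hd95(a2, b2), s * hd95(a, b), tolerance = 1e-12)
  expect_equal(hd_max(a2, b2), s * hd_max(a, b), tolerance = 1e-12)
  expect_equal(dsc(a2, b2), dsc(a, b))
})

test_that("equal-radius offset spheres reproduce the closed-form HD and lens DSC", {
  r <- 10; d <- 4; h <- 0.5
  grid <- c(56L, 48L, 48L)
  a <- sphere_mask(c(11, 12, 12), r, rep(h, 3), grid)
  b <- sphere_mask(c(11 + d, 12, 12), r, rep(h, 3), grid)
  hd <- hd_max(a, b)
  expect_lt(abs(hd - d), sqrt(3) * h)          # within one voxel diagonal
  lens <- pi * (4 * r + d) * (2 * r - d)^2 / 12
  dsc_closed <- lens / (4 / 3 * pi * r^3)
  expect_lt(abs(dsc(a, b) - dsc_closed) / dsc_closed, 0.02)
})

test_that("dsc shrinks and hd95 grows as a convex solid is translated further", {
  base <- array(0L, c(30, 12, 12))
  base[3:10, 3:10, 3:10] <- 1L
  a <- label_volume(base)
  prev_dsc <- Inf
  prev_hd <- -Inf
  for (t_vox in 1:4) {
    sh <- array(0L, c(30, 12, 12))
    sh[(3 + t_vox):(10 + t_vox), 3:10, 3:10] <- 1L
    b <- label_volume(sh)
    expect_lte(dsc(a, b), prev_dsc)
    expect_gte(hd95(a, b), prev_hd)
    prev_dsc <- dsc(a, b)
    prev_hd <- hd95(a, b)
  }
})

test_that("pair_metrics bundles consistent values", {
  set.seed(61)
  a <- random_mask()
  b <- random_mask()
  pm <- pair_metrics(a, b)
  expect_named(pm, c("dsc", "hd", "hd95", "volume_a", "volume_b"))
  expect_equal(pm$dsc, dsc(a, b))
  expect_equal(pm$hd95, hd95(a, b))
  expect_equal(pm$volume_a, volume_mm3(a))
  expect_lte(pm$hd95, pm$hd + 1e-12)
})
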