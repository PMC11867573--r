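test_that("icc_2_1 hits its algebraic limits", {
  # identical raters, nonzero subject variance: perfect agreement
  m <- cbind(1:6, 1:6)
  res <- icc_2_1(m)
  expect_equal(res$icc, 1)
  expect_true(res$good)
  expect_equal(res$n_subjects, 6)
  expect_equal(res$n_raters, 2)

  # no subject variance, independent rater noise: ICC near 0 at large n
  set.seed(101)
  m0 <- matrix(rnorm(2000), ncol = 2)
  expect_lt(abs(icc_2_1(m0)$icc), 0.05)
  expect_false(icc_2_1(m0)$good)

  expect_error(icc_2_1(cbind(1:2)), "raters")
  expect_error(icc_2_1(rbind(c(1, 2))), "subjects")
  expect_error(icc_2_1(cbind(c(1, NA), c(1, 2))), "missing")
})

test_that("icc_2_1 recovers the variance-components ICC", {
  # subjects N(0, 4), rater offsets with between-rater variance 1, residual
  # N(0, 1): population ICC(2,1) = 4 / (4 + 1 + 1) = 2/3
  set.seed(1)
  p <- rnorm(1000, 0, 2)
  r <- c(-1, 1) * sqrt(1 / 2)
  e <- matrix(rnorm(2000), ncol = 2)
  m <- outer(p, c(1, 1)) + matrix(r, 1000, 2, byrow = TRUE) + e
  expect_lt(abs(icc_2_1(m)$icc - 2 / 3), 0.03)
})

test_that("icc_2_1 agrees with an independent aov decomposition", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k) +
      outer(rnorm(n, sd = runif(1, 0, 2)), rep(1, k))
    expect_equal(icc_2_1(m)$icc, oracle_icc_aov(m), tolerance = 1e-9)
  }
})

test_that("icc_2_1 is invariant to shift and positive scaling", {
  set.seed(23)
  m <- matrix(rnorm(60), 20, 3) + outer(rnorm(20, sd = 2), rep(1, 3))
  base <- icc_2_1(m)$icc
  expect_equal(icc_2_1(m + 17.3)$icc, base, tolerance = 1e-12)
  expect_equal(icc_2_1(m * 4.2)$icc, base, tolerance = 1e-12)
  expect_equal(icc_2_1(m * 0.01 - 5)$icc, base, tolerance = 1e-9)
})

test_that("wilcoxon exact path matches textbook enumeration", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  expect_equal(res$statistic, 3)   # rank sum of x
  expect_false(res$significant)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    repeat {
      x <- round(rnorm(n, 0, 5), 3)
      y <- round(rnorm(m, 1, 5), 3)
      if (!any(duplicated(c(x, y)))) break
    }
    res <- wilcoxon_rank_sum(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, oracle_wilcox_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("wilcoxon path selection and degenerate inputs behave as documented", {
  # identical samples sit at the null centre: p = 1
  x <- c(1.5, 2.5, 3.5)
  expect_equal(wilcoxon_rank_sum(x, x)$p_value, 1)
  # large samples take the normal approximation
  set.seed(37)
  big <- wilcoxon_rank_sum(rnorm(50), rnorm(60))
  expect_equal(big$method, "normal_approx")
  # ties force the approximation even for small n
  tied <- wilcoxon_rank_sum(c(1, 2, 2), c(2, 3))
  expect_equal(tied$method, "normal_approx")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
  # paired signed-rank variant is available behind the flag
  pr <- wilcoxon_rank_sum(c(1, 2, 3, 5), c(2, 3, 5, 9), paired = TRUE)
  expect_s3_class(pr, "rank_sum_test")
  expect_error(wilcoxon_rank_sum(1:3, 1:4, paired = TRUE), "equal length")
})

test_that("a strong location shift is detected as significant", {
  set.seed(41)
  res <- wilcoxon_rank_sum(rnorm(40), rnorm(40) + 3)
  expect_true(res$significant)
  expect_lt(res$p_value, 1e-6)
})

test_that("summarize_mean_sd formats groups like a study table", {
  rec <- tibble::tibble(
    metric = "dsc",
    structure = rep(c("bladder", "rectum"), each = 3),
    comparison = "T1WI",
    value = c(0.9, 0.9, 0.9, 0.8, 1.0, NA)
  )
  s <- summarize_mean_sd(rec, metric, structure, comparison)
  b <- s[s$structure == "bladder", ]
  expect_equal(b$formatted, "0.900 ± 0.000")
  r <- s[s$structure == "rectum", ]
  expect_equal(r$n, 2L)          # NA dropped, not imputed
  expect_equal(r$mean, 0.9)
  expect_equal(r$sd, sqrt(0.02), tolerance = 1e-9)
  expect_equal(r$formatted, "0.900 ± 0.141")

  one <- summarize_mean_sd(
    tibble::tibble(metric = "dsc", structure = "bladder",
                   comparison = "T1WI", value = 0.5),
    metric, structure, comparison
  )
  expect_true(is.na(one$sd))

  empty <- summarize_mean_sd(rec[0, ], metric, structure, comparison)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("n", "mean", "sd", "formatted") %in% names(empty)))
})

test_that("tidy and glance methods return tibbles", {
  t1 <- generics::tidy(icc_2_1(cbind(1:5, c(1, 2, 3, 5, 5))))
  expect_s3_class(t1, "tbl_df")
  expect_true(all(c("icc", "good") %in% names(t1)))
  t2 <- generics::tidy(wilcoxon_rank_sum(1:4, 5:9))
  expect_s3_class(t2, "tbl_df")
  expect_true(all(c("statistic", "p_value", "method") %in% names(t2)))
})
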