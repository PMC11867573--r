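#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single measures
#'
#' The Shrout–Fleiss ICC(2,1) treats both subjects (here: patients) and
#' raters (observers, or sequences) as random samples and asks how much of
#' the total variance — including systematic rater offsets — is
#' between-subject variance. From the two-way ANOVA mean squares (MSR
#' between subjects, MSC between raters, MSE residual) with n subjects and
#' k raters:
#'
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#'
#' Values above 0.75 are conventionally read as good agreement; negative
#' estimates are reported as computed rather than clipped at zero.
#'
#' @param data Numeric matrix or data frame, subjects in rows, raters in
#'   columns; at least 2 of each, no missing cells.
#' @return An object of class `icc_result` with fields `icc`, `n_subjects`,
#'   `n_raters`, `ms_rows`, `ms_cols`, `ms_error` and the interpretation
#'   flag `good` (`icc > 0.75`). Use [generics::tidy()] for a tibble.
#' @examples
#' m <- cbind(c(1, 2, 3, 4), c(1.1, 2. , 3.2, 3.9))
#' icc_2_1(m)
#' @export
icc_2_1 <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("`data` must be numeric")
  if (anyNA(m)) stop("`data` must have no missing cells")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L) stop("need at least 2 subjects")
  if (k < 2L) stop("need at least 2 raters")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- max(ss_error / ((n - 1) * (k - 1)), 0)

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (denom == 0) {
    # all cells identical: no disagreement and no subject variance to
    # apportion; report perfect agreement
    1
  } else {
    (msr - mse) / denom
  }
  structure(
    list(icc = icc, n_subjects = n, n_raters = k,
         ms_rows = msr, ms_cols = msc, ms_error = mse,
         good = icc > 0.75),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(2,1) = %.4f (%d subjects x %d raters) — %s agreement\n",
    x$icc, x$n_subjects, x$n_raters, if (x$good) "good" else "poor"
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, n_subjects = x$n_subjects, n_raters = x$n_raters,
    ms_rows = x$ms_rows, ms_cols = x$ms_cols, ms_error = x$ms_error,
    good = x$good
  )
}

#' @export
glance.icc_result <- function(x, ...) tidy.icc_result(x)

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided rank-sum (Mann–Whitney) test. Ranks use midranks for ties; the
#' p-value comes from the exact null distribution when both samples are
#' small (`min(n, m) <= 10`) and tie-free, and otherwise from the normal
#' approximation with tie and continuity corrections. The `method` field
#' records which path ran; `significant` applies the conventional
#' `p < 0.05` threshold. A paired signed-rank variant is available via
#' `paired = TRUE` for designs where the two samples are per-patient pairs.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param paired Use the Wilcoxon signed-rank test on paired values instead
#'   of the rank-sum test.
#' @return An object of class `rank_sum_test` with fields `statistic` (the
#'   rank sum of `x`; for the paired variant the signed-rank statistic),
#'   `p_value`, `significant`, `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))
#' @export
wilcoxon_rank_sum <- function(x, y, paired = FALSE) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    d <- x - y
    ties <- any(duplicated(abs(d[d != 0]))) || any(d == 0)
    exact <- length(d) <= 25 && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = exact, correct = TRUE)
    )
    stat <- unname(wt$statistic)
  } else {
    ties <- any(duplicated(c(x, y)))
    exact <- min(length(x), length(y)) <= 10 && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)
    )
    # report the rank-sum statistic W = U + n(n+1)/2 of sample x
    stat <- unname(wt$statistic) + length(x) * (length(x) + 1) / 2
  }
  p <- min(unname(wt$p.value), 1)
  structure(
    list(statistic = stat, p_value = p, significant = p < 0.05,
         method = if (exact) "exact" else "normal_approx"),
    class = "rank_sum_test"
  )
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon test: statistic = %g, p = %.4g (%s)%s\n",
              x$statistic, x$p_value, x$method,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 significant = x$significant, method = x$method)
}

#' @export
glance.rank_sum_test <- function(x, ...) tidy.rank_sum_test(x)

#' Aggregate metric records as mean ± SD
#'
#' Groups long-format metric records and reports, per group, the number of
#' available values, their mean, sample standard deviation (denominator
#' n - 1) and a `"mean ± sd"` string formatted to 3 decimals — the layout of
#' per-structure, per-comparison summary tables in contouring studies.
#' Records whose `value` is `NA` ("not available", e.g. an absent structure)
#' are dropped before aggregation and never imputed as zeros; single-record
#' groups report `NA` for the SD.
#'
#' @param records A data frame with a numeric `value` column.
#' @param ... Grouping columns (tidy-select), e.g. `metric, structure,
#'   comparison`.
#' @return A tibble with the grouping columns plus `n`, `mean`, `sd`,
#'   `formatted`.
#' @export
summarize_mean_sd <- function(records, ...) {
  if (!nrow(records)) {
    return(tibble::tibble(n = integer(), mean = numeric(), sd = numeric(),
                          formatted = character()))
  }
  records |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), NA_real_),
      .by = c(...)
    ) |>
    dplyr::mutate(
      formatted = ifelse(
        is.na(.data$sd),
        sprintf("%.3f", .data$mean),
        sprintf("%.3f ± %.3f", .data$mean, .data$sd)
      )
    )
}
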