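# Two-group comparison machinery: t-tests computable either from raw samples
# or from printed summary statistics (n, mean, SD per group), categorical
# tests with the usual chi-square/Fisher switch, and Pearson correlation.

#' Group summary (n, mean, SD)
#'
#' A minimal container for the per-group summaries printed in cohort tables,
#' so published results can be re-tested without the raw data.
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @return a list of class `"group_summary"`.
#' @export
#' @examples
#' group_summary(83, 70.54, 6.95)
group_summary <- function(n, mean, sd) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2, n == round(n))
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0, is.finite(sd))
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

summarize_sample <- function(x) {
  if (length(x) < 2L || anyNA(x)) {
    stop("each sample needs >= 2 non-missing values", call. = FALSE)
  }
  group_summary(length(x), mean(x), stats::sd(x))
}

test_result <- function(statistic, df, p_value, method) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value, method = method),
    class = "two_group_test"
  )
}

#' @export
print.two_group_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic, digits = 6),
      if (!is.null(x$df) && !is.na(x$df)) paste(", df =", format(x$df, digits = 6)) else "",
      ", p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Welch's t-test from printed group summaries
#'
#' The unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, computed from (n, mean, SD) pairs, so p-values printed in a
#' publication can be reproduced from its summary table alone.
#'
#' @param g1,g2 [group_summary()] objects (or lists with `n`, `mean`, `sd`).
#' @return a `two_group_test` with `statistic`, fractional `df`, two-sided
#'   `p_value` and `method`.
#' @export
#' @examples
#' # sphericity row of a case-control table: p ~ 0.0062
#' welch_t_from_summary(group_summary(83, 70.54, 6.95),
#'                      group_summary(74, 66.58, 10.34))
welch_t_from_summary <- function(g1, g2) {
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  if (v1 + v2 == 0) {
    if (g1$mean == g2$mean) {
      stop("both groups degenerate (sd = 0) with equal means: statistic undefined",
           call. = FALSE)
    }
    return(test_result(sign(g1$mean - g2$mean) * Inf, NA_real_, 0,
                       "Welch two-sample t-test (from summaries)"))
  }
  tstat <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  test_result(tstat, df, 2 * stats::pt(-abs(tstat), df),
              "Welch two-sample t-test (from summaries)")
}

#' Welch's t-test from raw samples
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = FALSE`, returned in
#' the same shape as [welch_t_from_summary()]; by construction the two agree
#' to machine precision when applied to a sample and its own summaries.
#'
#' @param x1,x2 numeric vectors (>= 2 values each).
#' @return a `two_group_test`.
#' @export
welch_t_raw <- function(x1, x2) {
  summarize_sample(x1)
  summarize_sample(x2)
  tt <- stats::t.test(x1, x2, var.equal = FALSE)
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              "Welch two-sample t-test")
}

#' Pooled-variance Student's t-test from group summaries
#'
#' @inheritParams welch_t_from_summary
#' @return a `two_group_test` with `df = n1 + n2 - 2`.
#' @export
student_t_pooled <- function(g1, g2) {
  df <- g1$n + g2$n - 2
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  if (sp2 == 0) {
    if (g1$mean == g2$mean) {
      stop("both groups degenerate (sd = 0) with equal means: statistic undefined",
           call. = FALSE)
    }
    return(test_result(sign(g1$mean - g2$mean) * Inf, df, 0,
                       "Pooled two-sample t-test (from summaries)"))
  }
  tstat <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  test_result(tstat, df, 2 * stats::pt(-abs(tstat), df),
              "Pooled two-sample t-test (from summaries)")
}

#' Chi-square or Fisher's exact test for a 2-by-k contingency table
#'
#' Pearson's chi-square without continuity correction by default; for 2x2
#' tables where any expected cell count falls below 5 or any observed cell
#' is zero, Fisher's exact test is used instead, mirroring standard
#' reporting practice for sparse case-control tables.
#'
#' @param tab 2-by-k matrix of non-negative integer counts, k >= 2.
#' @param correct apply Yates continuity correction to 2x2 chi-square tests.
#' @param force `"auto"` (default switch rule), `"chisq"` or `"fisher"`.
#' @return a `two_group_test` (statistic/df are `NA` for Fisher).
#' @export
#' @examples
#' chi_square_or_fisher(rbind(c(10, 40), c(30, 20)))
chi_square_or_fisher <- function(tab, correct = FALSE,
                                 force = c("auto", "chisq", "fisher")) {
  force <- match.arg(force)
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L || ncol(tab) < 2L) {
    stop("`tab` must be a 2-by-k table with k >= 2", call. = FALSE)
  }
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- force == "fisher" ||
    (force == "auto" && ncol(tab) == 2L && (any(expected < 5) || any(tab == 0)))
  if (use_fisher) {
    ft <- stats::fisher.test(tab)
    test_result(NA_real_, NA_real_, ft$p.value, "Fisher's exact test")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    test_result(unname(ct$statistic), unname(ct$parameter), ct$p.value,
                if (correct) "Pearson chi-square (Yates)" else "Pearson chi-square")
  }
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 3, no missing values.
#' @return the correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must match in length", call. = FALSE)
  if (length(x) < 3L || anyNA(x) || anyNA(y)) {
    stop("need >= 3 complete pairs", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}
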