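# Empirical ROC analysis. The curve and its AUC are computed directly from
# the rank structure of the scores (AUC as the Mann-Whitney probability of
# correct ordering, ties counted 1/2); the DeLong confidence interval for the
# AUC comes from pROC.

#' Empirical ROC curve with AUC and DeLong confidence interval
#'
#' Builds the empirical ROC over all distinct score thresholds. With
#' `direction = "higher_riskier"` a subject is called a case when its score
#' is >= the threshold; with `"lower_riskier"` when it is <= the threshold.
#' A risk marker whose low values mark cases can therefore be analyzed
#' either in its raw orientation (AUC below 0.5) or flipped.
#'
#' @param scores numeric marker values, one per subject.
#' @param labels binary outcome (logical, 0/1, or 2-level factor with the
#'   second level the case class).
#' @param direction `"higher_riskier"` (default) or `"lower_riskier"`.
#' @param conf_level confidence level for the DeLong AUC interval.
#' @return a list of class `"roc_curve_fit"`: `points` (data frame of
#'   `threshold`, `fpr`, `tpr`, one row per distinct threshold plus the
#'   (0,0) origin), `auc`, `ci_low`, `ci_high`, `direction`, `n_cases`,
#'   `n_controls`.
#' @export
#' @examples
#' roc_curve(c(1, 2, 3, 4, 5, 6), c(0, 0, 1, 0, 1, 1))
roc_curve <- function(scores, labels,
                      direction = c("higher_riskier", "lower_riskier"),
                      conf_level = 0.95) {
  direction <- match.arg(direction)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- check_binary(labels, "labels")
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must match in length", call. = FALSE)
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("`scores` must be finite and non-missing", call. = FALSE)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }

  s <- if (direction == "higher_riskier") scores else -scores
  # Mann-Whitney AUC via midranks: ties contribute 1/2 automatically.
  r <- rank(s)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- cumsum(vapply(thr, function(t) sum(s[labels == 1] == t), 0)) / n1
  fpr <- cumsum(vapply(thr, function(t) sum(s[labels == 0] == t), 0)) / n0
  pts <- data.frame(
    threshold = c(Inf, if (direction == "higher_riskier") thr else -thr),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )

  proc <- pROC::roc(
    response = labels, predictor = scores, levels = c(0, 1),
    direction = if (direction == "higher_riskier") "<" else ">",
    quiet = TRUE
  )
  # pROC emits an advisory warning for degenerate (AUC = 0 or 1) curves
  ci <- as.numeric(suppressWarnings(
    pROC::ci.auc(proc, conf.level = conf_level, method = "delong")
  ))

  structure(
    list(
      points = pts, auc = auc, ci_low = ci[1], ci_high = ci[3],
      conf_level = conf_level, direction = direction,
      n_cases = n1, n_controls = n0
    ),
    class = "roc_curve_fit"
  )
}

#' @export
print.roc_curve_fit <- function(x, ...) {
  cat(sprintf(
    "Empirical ROC (%d cases / %d controls, %s)\n  AUC = %.4f  [%g%% DeLong CI %.4f-%.4f]\n",
    x$n_cases, x$n_controls, x$direction, x$auc,
    100 * x$conf_level, x$ci_low, x$ci_high
  ))
  invisible(x)
}

#' Youden-optimal operating point of a ROC curve
#'
#' Returns the finite threshold maximizing Youden's J = sensitivity +
#' specificity - 1; ties are broken toward higher sensitivity, then toward
#' the earlier (more permissive) threshold.
#'
#' @param curve a [roc_curve()] result.
#' @return a list with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve_fit"))
  pts <- curve$points[is.finite(curve$points$threshold), , drop = FALSE]
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[pts$tpr[best] == max(pts$tpr[best])]
  best <- best[1L]
  list(
    threshold = pts$threshold[best],
    sensitivity = pts$tpr[best],
    specificity = 1 - pts$fpr[best],
    youden_j = j[best]
  )
}

#' Tertile analysis of a continuous marker against a binary outcome
#'
#' Splits the marker at its empirical 1/3 and 2/3 quantiles (linear
#' interpolation, the default quantile definition), assigns boundary ties to
#' the upper tertile so the bin sizes follow the quantile positions (e.g.
#' 52/52/53 at n = 157 with distinct values), and reports the percentage of
#' cases in each tertile together with a 2-by-3 chi-square test.
#'
#' @param values numeric marker values.
#' @param labels binary outcome, as in [roc_curve()].
#' @return a list with `breaks` (the two quantiles), `n` (per-tertile
#'   totals), `n_cases`, `percent_cases` and `test` (a `two_group_test`).
#' @export
tertile_analysis <- function(values, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- check_binary(labels, "labels")
  if (length(values) < 3L || length(values) != length(labels)) {
    stop("need >= 3 values with matching labels", call. = FALSE)
  }
  if (anyNA(values)) stop("`values` must be non-missing", call. = FALSE)
  q <- stats::quantile(values, c(1, 2) / 3, type = 7, names = FALSE)
  tert <- 1L + (values >= q[1]) + (values >= q[2])
  n <- tabulate(tert, nbins = 3L)
  if (any(n == 0L)) {
    stop("degenerate binning: heavy ties leave an empty tertile", call. = FALSE)
  }
  n_cases <- vapply(1:3, function(k) sum(labels[tert == k]), 0)
  tab <- rbind(cases = n_cases, controls = n - n_cases)
  list(
    breaks = q,
    n = n,
    n_cases = n_cases,
    percent_cases = 100 * n_cases / n,
    test = chi_square_or_fisher(tab)
  )
}
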