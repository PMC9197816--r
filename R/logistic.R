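# Logistic regression wrapper producing the odds-ratio tables used in
# case-control reporting, with explicit convergence and separation
# diagnostics instead of silent output.

#' Fit a logistic regression and report odds ratios
#'
#' Maximum-likelihood fit via [stats::glm()] (iteratively reweighted least
#' squares), with Wald standard errors and 95% confidence intervals as
#' `exp(coef +/- 1.96 * SE)`. Quasi-separation is flagged whenever any
#' non-intercept coefficient exceeds `separation_bound` in absolute value
#' (complete or near-complete separation drives coefficients toward
#' infinity), and non-convergence is flagged rather than hidden.
#'
#' @param x data frame or numeric matrix of covariates (no intercept column;
#'   one is added). Logical columns are treated as 0/1.
#' @param y binary outcome: logical, 0/1 numeric, or 2-level factor
#'   (second level = event).
#' @param separation_bound absolute coefficient size beyond which
#'   quasi-separation is flagged.
#' @param conf_z normal quantile for the confidence interval (1.96 for 95%).
#' @return a list of class `"logistic_fit"`: `table` (data frame with
#'   `term`, `coefficient`, `standard_error`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`), `converged`, `n_iterations`, `separation_flag`,
#'   `loglik`, `n`, and the underlying `glm` object.
#' @export
#' @examples
#' x <- data.frame(exposed = c(rep(1, 30), rep(0, 30)))
#' y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
#' logistic_fit(x, y)$table
logistic_fit <- function(x, y, separation_bound = 15, conf_z = 1.96) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1)) || anyNA(y)) {
    stop("`y` must be binary with no missing values", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("outcome is constant: logistic regression undefined", call. = FALSE)
  }
  if (is.null(x)) {
    x <- data.frame(row.names = seq_along(y))
  }
  x <- as.data.frame(x)
  if (ncol(x) > 0 && nrow(x) != length(y)) {
    stop("`x` and `y` must have matching length", call. = FALSE)
  }
  x[] <- lapply(x, function(col) if (is.logical(col)) as.integer(col) else col)
  dat <- cbind(.outcome = y, x)
  mm <- stats::model.matrix(.outcome ~ ., data = dat)
  if (qr(mm)$rank < ncol(mm)) {
    stop("design matrix is rank-deficient after adding the intercept; ",
         "drop collinear covariates", call. = FALSE)
  }
  fit <- stats::glm(.outcome ~ ., family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-14, maxit = 100))
  coefs <- summary(fit)$coefficients
  tab <- data.frame(
    term = rownames(coefs),
    coefficient = coefs[, "Estimate"],
    standard_error = coefs[, "Std. Error"],
    odds_ratio = exp(coefs[, "Estimate"]),
    ci_low = exp(coefs[, "Estimate"] - conf_z * coefs[, "Std. Error"]),
    ci_high = exp(coefs[, "Estimate"] + conf_z * coefs[, "Std. Error"]),
    p_value = coefs[, "Pr(>|z|)"],
    row.names = NULL
  )
  sep <- any(abs(tab$coefficient[tab$term != "(Intercept)"]) > separation_bound)
  if (sep) {
    warning("possible quasi-separation: a coefficient exceeds ",
            separation_bound, " in absolute value", call. = FALSE)
  }
  if (!fit$converged) {
    warning("IRLS did not converge", call. = FALSE)
  }
  structure(
    list(
      table = tab, converged = fit$converged, n_iterations = fit$iter,
      separation_flag = sep, loglik = as.numeric(stats::logLik(fit)),
      n = length(y), glm = fit
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression (n = %d, %s in %d IRLS iterations)\n",
              x$n, if (x$converged) "converged" else "DID NOT CONVERGE",
              x$n_iterations))
  if (x$separation_flag) cat("  ** quasi-separation flagged **\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits = 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
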