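# Linear discriminant machinery for left atrial shape-based stroke-risk
# scoring: the published eight-coefficient score, two-class LDA re-fitting,
# leave-one-out cross-validated misclassification (PIC), multi-class
# canonical variates, and combination of the imaging score with a clinical
# risk score.

FEATURE_COLS <- c("a1", "b1", "a2", "b2", "a3", "b3", "lasp", "vc_scaled")

#' Published discriminant coefficients and threshold
#'
#' The eight coefficients of the published linear discriminant over the six
#' radii (mm), sphericity (percent) and scaled volume coefficient
#' (VC / 10000, mm^3 x 1e-4), and the published operating threshold.
#' The published function carries no explicit centering, so absolute score
#' levels (and hence the threshold) are only meaningful under the same
#' centering convention used when the function was derived; scores re-fitted
#' with [fit_lda()] on a new cohort should use that fit's own threshold.
#'
#' @format `la_discriminant_coefficients` is a named numeric vector of
#'   length 8; `la_discriminant_threshold` a single number.
#' @export
la_discriminant_coefficients <- c(
  a1 = 0.0161, a2 = -0.0192, a3 = 0.1076,
  b1 = -0.0016, b2 = -0.0694, b3 = 0.1321,
  lasp = -0.1102, vc_scaled = 0.0061
)

#' @rdname la_discriminant_coefficients
#' @export
la_discriminant_threshold <- -0.0863

#' Evaluate the published discriminant score
#'
#' The exact linear combination
#' `0.0161 A1 - 0.0192 A2 + 0.1076 A3 - 0.0016 B1 - 0.0694 B2 + 0.1321 B3
#'  - 0.1102 LASP + 0.0061 VC/10000`,
#' with no centering applied. Higher scores indicate the prior-stroke class.
#'
#' @param features data frame (or named list / named vector for a single
#'   patient) with columns `a1, b1, a2, b2, a3, b3` (mm), `lasp` (percent)
#'   and either `vc_scaled` (VC / 10000) or `vc` (mm^3, scaled internally).
#' @return numeric vector of scores, one per row.
#' @export
#' @examples
#' published_score(data.frame(
#'   a1 = 36, b1 = 36, a2 = 30, b2 = 30, a3 = 25, b3 = 25,
#'   lasp = 92.1, vc_scaled = 16.2
#' ))
published_score <- function(features) {
  if (!is.data.frame(features)) features <- as.data.frame(as.list(features))
  if (!"vc_scaled" %in% names(features) && "vc" %in% names(features)) {
    features$vc_scaled <- features$vc / 10000
  }
  missing <- setdiff(FEATURE_COLS, names(features))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(features[FEATURE_COLS])
  if (anyNA(x) || any(!is.finite(x))) {
    stop("features must be finite and non-missing", call. = FALSE)
  }
  unname(drop(x %*% la_discriminant_coefficients[FEATURE_COLS]))
}

#' Build the discriminant feature matrix from a cohort table
#'
#' Computes sphericity and the scaled volume coefficient from the radius
#' columns and returns the n-by-8 feature matrix the discriminant operates
#' on.
#'
#' @param cohort data frame with columns `a1, b1, a2, b2, a3, b3` (mm).
#' @inheritParams sphericity
#' @return numeric matrix with columns
#'   `a1, b1, a2, b2, a3, b3, lasp, vc_scaled`.
#' @export
discriminant_features <- function(cohort, sd_mode = c("sample", "population")) {
  r <- as_radii(cohort)
  cbind(r,
        lasp = sphericity(r, sd_mode),
        vc_scaled = volume_coefficient(r) / 10000)
}

prep_classes <- function(y) {
  if (is.logical(y) || (is.numeric(y) && all(y %in% c(0, 1)))) {
    y <- factor(y, levels = c(0, 1))
  }
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("`y` must have exactly two classes", call. = FALSE)
  y
}

# pooled within-class scatter and per-class stats; errors name collinearity
within_scatter <- function(x, y) {
  lev <- levels(y)
  W <- matrix(0, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  means <- matrix(NA_real_, length(lev), ncol(x),
                  dimnames = list(lev, colnames(x)))
  for (l in lev) {
    xi <- x[y == l, , drop = FALSE]
    means[l, ] <- colMeans(xi)
    W <- W + crossprod(sweep(xi, 2, means[l, ]))
  }
  list(W = W, means = means, n = tabulate(y))
}

solve_spd <- function(S, b) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch) && rcond(S) < 1e-12) ch <- NULL
  if (is.null(ch)) {
    ev <- eigen(S, symmetric = TRUE, only.values = FALSE)
    null_dir <- ev$vectors[, ncol(S)]
    worst <- colnames(S)[order(-abs(null_dir))[1:2]]
    stop("singular pooled within-class covariance; near-collinear features ",
         "include: ", paste(worst, collapse = ", "), call. = FALSE)
  }
  backsolve(ch, forwardsolve(t(ch), b))
}

#' Fit a two-class linear discriminant
#'
#' Fisher's linear discriminant under the Gaussian equal-covariance model:
#' the coefficient vector is `S^-1 (mu2 - mu1)` with `S` the pooled
#' within-class covariance (divisor n - 2), rescaled so the discriminant
#' score has unit pooled within-class variance. The classification
#' threshold on the score scale is the class-mean midpoint shifted by the
#' log prior ratio.
#'
#' @param x numeric feature matrix (n x p), e.g. [discriminant_features()].
#' @param y two-class labels; the second level (or 1 / `TRUE`) is the case
#'   class, which gets the larger discriminant mean.
#' @param priors `"empirical"` (class frequencies, default), `"equal"`, or a
#'   length-2 numeric vector summing to 1 (control, case).
#' @return a list of class `"lda_fit"`: `coefficients` (length p, unit
#'   within-class variance scaling), `means` (class means on the score
#'   scale), `class_means` (p-vector per class), `pooled_cov`, `priors`,
#'   `threshold`, `levels`, `n`.
#' @export
fit_lda <- function(x, y, priors = "empirical") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- prep_classes(y)
  if (nrow(x) != length(y)) stop("`x` and `y` must match in length", call. = FALSE)
  if (any(tabulate(y) < 2L)) stop("need >= 2 samples per class", call. = FALSE)
  ws <- within_scatter(x, y)
  n <- nrow(x)
  S <- ws$W / (n - 2)
  delta <- ws$means[2, ] - ws$means[1, ]
  w <- solve_spd(S, delta)
  scale <- sqrt(sum(w * (S %*% w)))
  if (!is.finite(scale) || scale <= 0) {
    stop("degenerate discriminant: zero between-class separation", call. = FALSE)
  }
  w <- w / scale
  m <- drop(ws$means %*% w)
  pr <- resolve_priors(priors, ws$n)
  structure(
    list(
      coefficients = w,
      means = m,
      class_means = ws$means,
      pooled_cov = S,
      priors = pr,
      threshold = unname((m[1] + m[2]) / 2 - log(pr[2] / pr[1]) / (m[2] - m[1])),
      levels = levels(y),
      n = ws$n
    ),
    class = "lda_fit"
  )
}

resolve_priors <- function(priors, counts) {
  if (identical(priors, "empirical")) {
    pr <- counts / sum(counts)
  } else if (identical(priors, "equal")) {
    pr <- c(0.5, 0.5)
  } else {
    pr <- as.numeric(priors)
    if (length(pr) != 2L || any(pr <= 0) || abs(sum(pr) - 1) > 1e-8) {
      stop("`priors` must be \"empirical\", \"equal\", or two positive ",
           "numbers summing to 1", call. = FALSE)
    }
  }
  pr
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf(
    "Two-class linear discriminant (%s: n = %d, %s: n = %d)\n",
    x$levels[1], x$n[1], x$levels[2], x$n[2]
  ))
  cat("  score means:", sprintf("%.4f / %.4f", x$means[1], x$means[2]),
      " threshold:", sprintf("%.4f", x$threshold), "\n")
  cat("  coefficients:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Discriminant scores for new observations
#'
#' @param m an [fit_lda()] model.
#' @param x feature matrix with the model's columns.
#' @return numeric score vector (unit pooled within-class variance scale).
#' @export
discriminant_scores <- function(m, x) {
  stopifnot(inherits(m, "lda_fit"))
  x <- as.matrix(x)
  if (ncol(x) != length(m$coefficients)) {
    stop("feature matrix does not match the fitted model", call. = FALSE)
  }
  drop(x %*% m$coefficients)
}

#' Posterior probability of the case class
#'
#' Bayes posterior under the equal-covariance Gaussian model: on the score
#' scale both classes are N(mean_k, 1), so the posterior log-odds of the
#' case class are `log(p2/p1) + (s - (m1+m2)/2) (m2 - m1)`, a monotone
#' function of the discriminant score.
#'
#' @inheritParams discriminant_scores
#' @return probabilities in (0, 1) of membership in the case (second) class.
#' @export
posterior_probability <- function(m, x) {
  s <- discriminant_scores(m, x)
  mu <- unname(m$means)
  unname(stats::plogis(log(m$priors[2] / m$priors[1]) +
                         (s - (mu[1] + mu[2]) / 2) * (mu[2] - mu[1])))
}

#' Classify observations with a fitted discriminant
#'
#' @inheritParams discriminant_scores
#' @return factor of predicted class labels.
#' @export
classify_lda <- function(m, x) {
  s <- discriminant_scores(m, x)
  factor(m$levels[1L + (s > m$threshold)], levels = m$levels)
}

#' Leave-one-out cross-validated probability of incorrect classification
#'
#' For each subject the discriminant is re-estimated on the remaining n - 1
#' subjects and the held-out subject is classified; PIC is the fraction
#' misclassified. The default implementation updates the class means and the
#' pooled within-class scatter by rank-one downdating rather than refitting
#' from scratch; `method = "refit"` performs the naive refit per fold (the
#' two are algebraically identical). The per-fold scores are all expressed
#' with the case class on the positive side, so the cross-validated
#' posterior probabilities are comparable across folds.
#'
#' Two threshold conventions are reported: `pic` classifies each held-out
#' subject with its own fold's Bayes rule (threshold fixed before the fold's
#' prediction is seen), while `pic_optimized` re-optimizes a single common
#' cutoff on the pooled cross-validated posteriors afterwards (sweeping all
#' midpoints, ties toward the lower threshold) — an optimistic variant
#' corresponding to "optimal selection of the threshold" after
#' cross-validation.
#'
#' @inheritParams fit_lda
#' @param method `"downdate"` (fast, default) or `"refit"` (naive loop).
#' @return a list of class `"loocv_pic"`: `pic`, `pic_optimized`,
#'   `optimized_cutoff` (on the posterior scale), `scores` (LOOCV
#'   discriminant scores), `posterior` (LOOCV case posteriors), `predicted`
#'   (Bayes-rule factor), `labels`, `n`, `method`.
#' @export
loocv_pic <- function(x, y, priors = "empirical",
                      method = c("downdate", "refit")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- prep_classes(y)
  n <- nrow(x)
  if (n != length(y)) stop("`x` and `y` must match in length", call. = FALSE)
  counts <- tabulate(y)
  if (any(counts < 3L)) {
    stop("need >= 3 samples per class so every leave-one-out fold keeps >= 2",
         call. = FALSE)
  }
  ws <- within_scatter(x, y)
  scores <- post <- numeric(n)
  pred <- integer(n)
  for (i in seq_len(n)) {
    if (method == "refit") {
      m <- tryCatch(
        fit_lda(x[-i, , drop = FALSE], y[-i], priors = priors),
        error = function(e) {
          stop(sprintf("leave-one-out fold %d degenerate: %s", i,
                       conditionMessage(e)), call. = FALSE)
        }
      )
      s <- discriminant_scores(m, x[i, , drop = FALSE])
      mu <- unname(m$means)
      pr <- m$priors
    } else {
      k <- as.integer(y[i])
      nk <- counts[k]
      d <- x[i, ] - ws$means[k, ]
      # downdated class mean and pooled scatter after removing sample i
      means_i <- ws$means
      means_i[k, ] <- (nk * ws$means[k, ] - x[i, ]) / (nk - 1)
      W_i <- ws$W - (nk / (nk - 1)) * tcrossprod(d)
      S_i <- W_i / (n - 3)
      delta <- means_i[2, ] - means_i[1, ]
      w <- tryCatch(
        solve_spd(S_i, delta),
        error = function(e) {
          stop(sprintf("leave-one-out fold %d degenerate: %s", i,
                       conditionMessage(e)), call. = FALSE)
        }
      )
      w <- w / sqrt(sum(w * (S_i %*% w)))
      s <- sum(w * x[i, ])
      mu <- unname(drop(means_i %*% w))
      fold_counts <- counts
      fold_counts[k] <- nk - 1L
      pr <- resolve_priors(priors, fold_counts)
    }
    scores[i] <- s
    post[i] <- stats::plogis(log(pr[2] / pr[1]) +
                               (s - (mu[1] + mu[2]) / 2) * (mu[2] - mu[1]))
    pred[i] <- 1L + (post[i] > 0.5)
  }
  truth <- as.integer(y)
  cuts <- sort(unique(post))
  cand <- c(0, (cuts[-1] + cuts[-length(cuts)]) / 2, 1)
  errs <- vapply(cand, function(t) sum((post > t) + 1L != truth), 0L)
  best <- which.min(errs) # which.min takes the first minimum: lower threshold
  structure(
    list(
      pic = mean(pred != truth),
      pic_optimized = errs[best] / n,
      optimized_cutoff = cand[best],
      scores = scores, posterior = post,
      predicted = factor(levels(y)[pred], levels = levels(y)),
      labels = y, n = n, method = method
    ),
    class = "loocv_pic"
  )
}

#' @export
print.loocv_pic <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out cross-validation (n = %d, %s)\n  PIC (per-fold Bayes rule)  = %.4f\n  PIC (post-hoc optimal cut) = %.4f at posterior cutoff %.4f\n",
    x$n, x$method, x$pic, x$pic_optimized, x$optimized_cutoff
  ))
  invisible(x)
}

#' Canonical variates for k-class discriminant analysis
#'
#' Eigen-decomposition of `W^-1 B` (within- and between-class scatter),
#' computed through a symmetric reduction via the Cholesky factor of `W`.
#' Variates are scaled to unit pooled within-class variance and ordered by
#' decreasing eigenvalue (projected between-class variance); at most
#' `min(k - 1, p)` variates exist. The sign of each variate is fixed so the
#' first class has non-positive mean, making the output deterministic.
#'
#' @param x numeric feature matrix (n x p).
#' @param y class labels (k >= 2 levels).
#' @param n_variates maximum number of variates to return (default 2).
#' @return a list: `scores` (n x m), `vectors` (p x m), `eigenvalues`
#'   (length m), `class_means` (k x m, on the variate scale), `levels`.
#' @export
canonical_variates <- function(x, y, n_variates = 2L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- droplevels(as.factor(y))
  k <- nlevels(y)
  if (k < 2L) stop("need at least two classes", call. = FALSE)
  if (any(tabulate(y) < 2L)) stop("need >= 2 samples per class", call. = FALSE)
  ws <- within_scatter(x, y)
  grand <- colMeans(x)
  B <- matrix(0, ncol(x), ncol(x))
  for (j in seq_len(k)) {
    d <- ws$means[j, ] - grand
    B <- B + ws$n[j] * tcrossprod(d)
  }
  U <- tryCatch(chol(ws$W), error = function(e) {
    stop("singular within-class scatter", call. = FALSE)
  })
  Ui <- backsolve(U, diag(ncol(x)))
  Msym <- t(Ui) %*% B %*% Ui
  ev <- eigen((Msym + t(Msym)) / 2, symmetric = TRUE)
  m <- min(k - 1L, ncol(x), n_variates)
  vecs <- Ui %*% ev$vectors[, seq_len(m), drop = FALSE]
  # unit pooled within-class variance: t(v) (W / (n - k)) v = 1
  vecs <- vecs * sqrt(nrow(x) - k)
  sc <- x %*% vecs
  first <- colMeans(sc[y == levels(y)[1], , drop = FALSE])
  flip <- ifelse(first > 0, -1, 1)
  vecs <- sweep(vecs, 2, flip, `*`)
  sc <- sweep(sc, 2, flip, `*`)
  colnames(sc) <- colnames(vecs) <- paste0("LD", seq_len(m))
  list(
    scores = sc, vectors = vecs, eigenvalues = ev$values[seq_len(m)],
    class_means = ws$means %*% vecs, levels = levels(y)
  )
}

#' Combine a discriminant score with a clinical risk score
#'
#' Fits logistic regressions of the outcome on the clinical score alone and
#' on the clinical score plus the discriminant score, and returns ROC curves
#' of the two fitted probability vectors, quantifying the added
#' discrimination from the imaging score. A constant (uninformative)
#' discriminant score reduces the combined model to the clinical one.
#'
#' @param disc_scores numeric discriminant scores.
#' @param clinical_scores numeric clinical risk scores (e.g. CHA2DS2-VASc).
#' @param labels binary outcome, as in [roc_curve()].
#' @return a list: `fit_alone`, `fit_combined` ([logistic_fit()] objects),
#'   `roc_alone`, `roc_combined` ([roc_curve()] objects), `auc_alone`,
#'   `auc_combined`.
#' @export
combine_with_clinical <- function(disc_scores, clinical_scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- check_binary(labels, "labels")
  fit_alone <- logistic_fit(data.frame(clinical = clinical_scores), labels)
  if (stats::sd(disc_scores) == 0) {
    fit_combined <- fit_alone
  } else {
    fit_combined <- logistic_fit(
      data.frame(clinical = clinical_scores, discriminant = disc_scores),
      labels
    )
  }
  roc_alone <- roc_curve(stats::fitted(fit_alone$glm), labels)
  roc_combined <- roc_curve(stats::fitted(fit_combined$glm), labels)
  list(
    fit_alone = fit_alone, fit_combined = fit_combined,
    roc_alone = roc_alone, roc_combined = roc_combined,
    auc_alone = roc_alone$auc, auc_combined = roc_combined$auc
  )
}
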