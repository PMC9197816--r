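test_that("published score is the exact printed linear combination", {
  z <- data.frame(a1 = 0, b1 = 0, a2 = 0, b2 = 0, a3 = 0, b3 = 0,
                  lasp = 0, vc_scaled = 0)
  expect_equal(published_score(z), 0)
  z$a3 <- 1
  expect_equal(published_score(z), 0.1076)

  f <- data.frame(a1 = 36, b1 = 36, a2 = 30, b2 = 30, a3 = 25, b3 = 25,
                  lasp = 92.1, vc_scaled = 16.2)
  # independent hand evaluation of the printed polynomial, term by term
  hand <- 0.0161 * 36 - 0.0192 * 30 + 0.1076 * 25 - 0.0016 * 36 -
    0.0694 * 30 + 0.1321 * 25 - 0.1102 * 92.1 + 0.0061 * 16.2
  expect_equal(published_score(f), hand, tolerance = 1e-12)

  # vc is scaled internally when vc_scaled is absent
  f2 <- f; f2$vc_scaled <- NULL; f2$vc <- 16.2 * 10000
  expect_equal(published_score(f2), hand, tolerance = 1e-12)
  expect_error(published_score(f[-1]), "missing feature")
})

test_that("published score is linear in the features", {
  withr_seed(17)
  for (i in 1:1000) {
    f <- as.data.frame(matrix(rnorm(8), 1, dimnames = list(NULL, c(
      "a1", "b1", "a2", "b2", "a3", "b3", "lasp", "vc_scaled"))))
    g <- as.data.frame(matrix(rnorm(8), 1, dimnames = list(NULL, names(f))))
    al <- rnorm(1); be <- rnorm(1)
    expect_equal(published_score(al * f + be * g),
                 al * published_score(f) + be * published_score(g),
                 tolerance = 1e-9)
  }
})

test_that("fit_lda recovers the closed-form pooled-covariance direction", {
  sigma <- matrix(c(2, 0.6, 0.6, 1), 2)
  d <- two_class_sample(400, 400, c(0, 0), c(3, 1), sigma, seed = 2)
  m <- fit_lda(d$x, d$y)
  # closed form from the sample pooled covariance and mean difference
  mu1 <- colMeans(d$x[d$y == "ctrl", ]); mu2 <- colMeans(d$x[d$y == "case", ])
  W <- crossprod(sweep(d$x[d$y == "ctrl", ], 2, mu1)) +
    crossprod(sweep(d$x[d$y == "case", ], 2, mu2))
  w_ref <- solve(W / (800 - 2), mu2 - mu1)
  cosine <- sum(m$coefficients * w_ref) /
    sqrt(sum(m$coefficients^2) * sum(w_ref^2))
  expect_equal(cosine, 1, tolerance = 1e-9)
  # unit pooled within-class variance of the discriminant score
  expect_equal(drop(t(m$coefficients) %*% (W / 798) %*% m$coefficients), 1,
               tolerance = 1e-9)
  # case class sits on the positive side
  expect_gt(m$means[2], m$means[1])
})

test_that("fit_lda agrees with an established LDA implementation", {
  skip_if_not_installed("MASS")
  d <- two_class_sample(60, 50, c(0, 0, 0), c(1.5, 0.5, -1), seed = 5)
  m <- fit_lda(d$x, d$y)
  ref <- MASS::lda(d$x, grouping = d$y)
  # scalings are proportional (both unit within-class variance, sign free)
  ratio <- m$coefficients / drop(ref$scaling)
  expect_equal(abs(ratio / ratio[1]), rep(1, 3), tolerance = 1e-6)
  expect_equal(abs(ratio[1]), 1, tolerance = 1e-6)
  # posteriors match MASS's Gaussian posteriors
  post <- posterior_probability(m, d$x)
  expect_equal(post, unname(predict(ref)$posterior[, "case"]),
               tolerance = 1e-8)
})

test_that("degenerate and label-symmetry behavior of fit_lda", {
  d <- two_class_sample(30, 30, c(0, 0), c(2, 0), seed = 3)
  expect_error(fit_lda(cbind(d$x, dup = d$x[, 1]), d$y), "singular")
  m1 <- fit_lda(d$x, d$y)
  m2 <- fit_lda(d$x, factor(d$y, levels = rev(levels(d$y))))
  expect_equal(m1$coefficients, -m2$coefficients, tolerance = 1e-10)
  expect_equal(unname(abs(m1$means[2] - m1$means[1])),
               unname(abs(m2$means[2] - m2$means[1])), tolerance = 1e-10)
  # a class with a single member cannot be refit
  idx <- c(1, 2, 31)
  expect_error(fit_lda(d$x[idx, ], d$y[idx]), "2 samples")
})

test_that("posterior probabilities follow the two-density Bayes computation", {
  d <- two_class_sample(200, 100, c(0, 0), c(2, 1), seed = 7)
  m <- fit_lda(d$x, d$y)
  s <- discriminant_scores(m, d$x)
  oracle <- m$priors[2] * dnorm(s, m$means[2], 1) /
    (m$priors[1] * dnorm(s, m$means[1], 1) +
       m$priors[2] * dnorm(s, m$means[2], 1))
  expect_equal(posterior_probability(m, d$x), oracle, tolerance = 1e-12)
  # midpoint of the class means with equal priors scores exactly 0.5
  meq <- fit_lda(d$x, d$y, priors = "equal")
  mid <- (meq$class_means[1, ] + meq$class_means[2, ]) / 2
  expect_equal(posterior_probability(meq, matrix(mid, 1)), 0.5,
               tolerance = 1e-10)
  expect_gt(posterior_probability(meq, meq$class_means[2, , drop = FALSE]), 0.5)
})

test_that("LOOCV PIC: separation, permutation baseline and oracle equality", {
  # wide-margin separation: no fold misclassifies
  d <- two_class_sample(20, 20, c(0, 0), c(12, 0), seed = 9)
  expect_equal(loocv_pic(d$x, d$y)$pic, 0)

  # label-shuffled data: error near one half
  d <- two_class_sample(100, 100, c(0, 0), c(3, 0), seed = 10)
  withr_seed(10)
  ysh <- sample(d$y)
  expect_gt(loocv_pic(d$x, ysh)$pic, 0.35)
  expect_lt(loocv_pic(d$x, ysh)$pic, 0.65)

  # fast downdating equals brute-force refitting and the refit method
  for (seed in 1:10) {
    n1 <- 15 + seed %% 10; n2 <- 12 + (2 * seed) %% 9
    d <- two_class_sample(n1, n2, c(0, 0, 0), c(1.2, -0.4, 0.6), seed = seed)
    fast <- loocv_pic(d$x, d$y)
    oracle <- brute_force_loocv(d$x, d$y)
    expect_identical(fast$pic, oracle$pic)
    expect_equal(fast$posterior, oracle$posterior, tolerance = 1e-9)
    expect_identical(fast$pic, loocv_pic(d$x, d$y, method = "refit")$pic)
  }
})

test_that("post-hoc threshold optimization never increases the error", {
  d <- two_class_sample(40, 35, c(0, 0), c(1.5, 0.3), seed = 12)
  r <- loocv_pic(d$x, d$y)
  expect_lte(r$pic_optimized, r$pic)
  # the optimized error matches an exhaustive sweep over posterior cutoffs
  errs <- sapply(c(0, sort(unique(r$posterior)), 1), function(t) {
    mean((r$posterior > t) != (as.integer(r$labels) == 2))
  })
  expect_equal(r$pic_optimized, min(errs))
})

test_that("canonical variates reduce to LDA for two classes and order eigenvalues", {
  d <- two_class_sample(50, 40, c(0, 0, 0), c(1, 2, -0.5), seed = 15)
  cv <- canonical_variates(d$x, d$y)
  expect_equal(ncol(cv$scores), 1L) # k - 1 = 1 variate
  m <- fit_lda(d$x, d$y)
  cosine <- abs(sum(cv$vectors[, 1] * m$coefficients)) /
    sqrt(sum(cv$vectors[, 1]^2) * sum(m$coefficients^2))
  expect_equal(cosine, 1, tolerance = 1e-8)
  # sign convention: first class non-positive on each variate
  expect_lte(mean(cv$scores[d$y == levels(d$y)[1], 1]), 0)

  # three classes with collinear means: second eigenvalue ~ 0
  withr_seed(16)
  x <- rbind(matrix(rnorm(200), 100, 2),
             sweep(matrix(rnorm(200), 100, 2), 2, c(3, 3), `+`),
             sweep(matrix(rnorm(200), 100, 2), 2, c(6, 6), `+`))
  y3 <- rep(c("a", "b", "c"), each = 100)
  cv3 <- canonical_variates(x, y3)
  expect_equal(ncol(cv3$scores), 2L)
  expect_gte(cv3$eigenvalues[1], cv3$eigenvalues[2])
  expect_lt(cv3$eigenvalues[2] / cv3$eigenvalues[1], 0.05)
})

test_that("re-fitting recovers the direction of a known generating discriminant", {
  # classes built so the population discriminant IS the published vector:
  # with identity within-class covariance, delta-mu proportional to it
  w <- unname(la_discriminant_coefficients[c("a1", "b1", "a2", "b2",
                                             "a3", "b3", "lasp", "vc_scaled")])
  delta <- 2 * w / sqrt(sum(w^2))
  d <- two_class_sample(2500, 2500, rep(0, 8), delta, seed = 20)
  m <- fit_lda(d$x, d$y)
  cosine <- sum(m$coefficients * w) / sqrt(sum(m$coefficients^2) * sum(w^2))
  expect_gte(cosine, 0.95)
})

test_that("combining a discriminant with a clinical score behaves at the limits", {
  withr_seed(22)
  n <- 300
  chads <- sample(0:6, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(chads - 3))
  y[1:2] <- c(0, 1)

  # constant discriminant adds nothing
  r <- combine_with_clinical(rep(0.7, n), chads, y)
  expect_equal(r$auc_combined, r$auc_alone)

  # discriminant equal to the outcome indicator is perfect (the fit
  # separates, which the logistic module flags by design)
  r <- suppressWarnings(combine_with_clinical(as.numeric(y), chads, y))
  expect_equal(r$auc_combined, 1)

  # two independent signals: the combination beats either alone
  withr_seed(23)
  disc <- rnorm(n)
  y2 <- rbinom(n, 1, plogis(0.8 * scale(chads) + 0.8 * disc))
  y2[1:2] <- c(0, 1)
  r <- combine_with_clinical(disc, chads, y2)
  expect_gte(r$auc_combined,
             max(r$auc_alone, roc_curve(disc, y2)$auc) - 1e-9)
})
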