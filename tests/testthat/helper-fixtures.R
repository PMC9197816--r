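# Shared fixtures: all generated in code, seeded per use.

# random strictly-positive radius matrix (n x 6)
random_radii <- function(n, seed, lo = 5, hi = 70) {
  withr_seed(seed)
  matrix(runif(6 * n, lo, hi), ncol = 6,
         dimnames = list(NULL, c("a1", "b1", "a2", "b2", "a3", "b3")))
}

# minimal seed helper for tests (tests own the global RNG)
withr_seed <- function(seed) set.seed(seed)

# a clinical profile with every component switched off
empty_profile <- function(n = 1) {
  data.frame(
    age = rep(50, n), sex = "male", chf = FALSE, hypertension = FALSE,
    diabetes = FALSE, prior_stroke_tia = FALSE, vascular_disease = FALSE,
    renal_disease = FALSE, liver_disease = FALSE, bleeding_history = FALSE,
    labile_inr = FALSE, alcohol_use = FALSE, nsaid_or_antiplatelet = FALSE
  )
}

# two Gaussian classes with common covariance; returns x, y
two_class_sample <- function(n1, n2, mu1, mu2, sigma = NULL, seed = 1) {
  withr_seed(seed)
  p <- length(mu1)
  if (is.null(sigma)) sigma <- diag(p)
  ch <- chol(sigma)
  x1 <- matrix(rnorm(n1 * p), n1, p) %*% ch
  x2 <- matrix(rnorm(n2 * p), n2, p) %*% ch
  x1 <- sweep(x1, 2, mu1, `+`)
  x2 <- sweep(x2, 2, mu2, `+`)
  list(
    x = rbind(x1, x2),
    y = factor(rep(c("ctrl", "case"), c(n1, n2)), levels = c("ctrl", "case"))
  )
}

# independent brute-force LOOCV oracle: refits via fit_lda per fold and
# applies the fold's Bayes rule on the posterior, mirroring the contract of
# loocv_pic() but through the public single-fit API only.
brute_force_loocv <- function(x, y, priors = "empirical") {
  y <- factor(y)
  n <- nrow(x)
  wrong <- 0L
  post <- numeric(n)
  for (i in seq_len(n)) {
    m <- fit_lda(x[-i, , drop = FALSE], y[-i], priors = priors)
    post[i] <- posterior_probability(m, x[i, , drop = FALSE])
    pred <- if (post[i] > 0.5) m$levels[2] else m$levels[1]
    wrong <- wrong + (pred != as.character(y[i]))
  }
  list(pic = wrong / n, posterior = post)
}

# brute-force AUC by counting correctly ordered case-control pairs
pair_count_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  total <- 0
  for (s in cases) {
    total <- total + sum(s > ctrls) + 0.5 * sum(s == ctrls)
  }
  total / (length(cases) * length(ctrls))
}
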