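test_that("Welch from summaries: degenerate and identical-group behavior", {
  g <- group_summary(20, 5, 1)
  r <- welch_t_from_summary(g, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(
    welch_t_from_summary(group_summary(5, 3, 0), group_summary(5, 3, 0)),
    "undefined"
  )
})

test_that("Welch raw equals Welch from the samples' own summaries", {
  for (seed in 1:20) {
    withr_seed(seed)
    x1 <- rnorm(5 + seed %% 13, mean = 1, sd = 2)
    x2 <- rnorm(7 + (3 * seed) %% 11, sd = 0.5 + seed / 10)
    raw <- welch_t_raw(x1, x2)
    fs <- welch_t_from_summary(
      group_summary(length(x1), mean(x1), sd(x1)),
      group_summary(length(x2), mean(x2), sd(x2))
    )
    expect_equal(raw$statistic, fs$statistic, tolerance = 1e-12)
    expect_equal(raw$df, fs$df, tolerance = 1e-12)
    expect_equal(raw$p_value, fs$p_value, tolerance = 1e-12)
  }
  expect_equal(welch_t_raw(1:5, 1:5)$p_value, 1)
})

test_that("Welch raw matches the textbook formula on a seeded sample", {
  withr_seed(99)
  x1 <- rnorm(30, 1, 2)
  x2 <- rnorm(40, 0, 1)
  v1 <- var(x1) / 30; v2 <- var(x2) / 40
  tstat <- (mean(x1) - mean(x2)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / 29 + v2^2 / 39)
  r <- welch_t_raw(x1, x2)
  expect_equal(r$statistic, tstat, tolerance = 1e-12)
  expect_equal(r$df, df, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
})

test_that("pooled t-test matches t.test(var.equal = TRUE) and Welch in the equal-variance limit", {
  x1 <- c(4.1, 5.2, 6.3)
  x2 <- c(3.0, 4.4, 5.1)
  r <- student_t_pooled(group_summary(3, mean(x1), sd(x1)),
                        group_summary(3, mean(x2), sd(x2)))
  tt <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$df, unname(tt$parameter))
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)

  # equal n and equal sd: identical statistic, df differs only through Welch
  g1 <- group_summary(25, 1.2, 2); g2 <- group_summary(25, 0.4, 2)
  expect_equal(student_t_pooled(g1, g2)$statistic,
               welch_t_from_summary(g1, g2)$statistic, tolerance = 1e-12)
  expect_equal(welch_t_from_summary(g1, g2)$df, 48, tolerance = 1e-9)
})

test_that("chi-square / Fisher switch follows the expected-count rule", {
  # identical group proportions: statistic 0, p = 1
  r <- chi_square_or_fisher(rbind(c(20, 30), c(40, 60)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_match(r$method, "chi-square")

  # (10,0 / 0,10): Fisher, p from exhaustive hypergeometric enumeration
  r <- chi_square_or_fisher(rbind(c(10, 0), c(0, 10)))
  expect_match(r$method, "Fisher")
  # P(two-sided) = 2 * P(X = 10) with X ~ Hypergeom(10, 10, 10)
  enum <- sum(sapply(0:10, function(k) {
    pk <- choose(10, k) * choose(10, 10 - k) / choose(20, 10)
    if (pk <= choose(10, 10)^2 / choose(20, 10) + 1e-12) pk else 0
  }))
  expect_equal(r$p_value, enum, tolerance = 1e-12)

  # 2x3 hand table vs hand-computed expecteds
  tab <- rbind(c(10, 20, 30), c(20, 20, 20))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  r <- chi_square_or_fisher(tab)
  expect_equal(r$statistic, stat, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, pchisq(stat, 2, lower.tail = FALSE), tolerance = 1e-12)

  # sparse 2x2 switches to Fisher automatically
  expect_match(chi_square_or_fisher(rbind(c(2, 30), c(1, 40)))$method, "Fisher")
  # but can be forced to chi-square
  expect_match(chi_square_or_fisher(rbind(c(2, 30), c(1, 40)),
                                    force = "chisq")$method, "chi-square")

  expect_error(chi_square_or_fisher(rbind(c(0, 0), c(5, 5))), "degenerate")
  expect_error(chi_square_or_fisher(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  withr_seed(7)
  x <- rnorm(100); y <- 0.3 * x + rnorm(100)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), oracle, tolerance = 1e-12)
  expect_error(pearson_correlation(1:4, 1:5), "length")
})
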