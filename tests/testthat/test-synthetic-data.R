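test_that("group generation is deterministic and respects its configuration", {
  cfg <- control_group_config()
  cfg$kappa <- 20
  g1 <- generate_group(cfg, seed = 123)
  g2 <- generate_group(cfg, seed = 123)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_group(cfg, seed = 124)))
  expect_equal(nrow(g1), 83)
  expect_true(all(g1$laa_morphology %in% 1:4))
  expect_true(all(g1$age >= 18 & g1$age <= 120))
  expect_true(all(g1$laa_volume_cm3 > 1))
  expect_true(all(as.matrix(g1[c("a1", "b1", "a2", "b2", "a3", "b3")]) > 0))
})

test_that("large kappa forces near-equal within-axis radii", {
  cfg <- control_group_config()
  cfg$kappa <- 1e6
  g <- generate_group(cfg, seed = 1, n = 200)
  expect_lt(max(abs(g$a1 - g$b1) / (g$a1 + g$b1)), 0.01)
  expect_lt(max(abs(g$a3 - g$b3) / (g$a3 + g$b3)), 0.01)
})

test_that("simulated diameters match the configured distributions at large n", {
  cfg <- stroke_group_config()
  cfg$kappa <- 15
  g <- generate_group(cfg, seed = 77, n = 5000)
  d <- derive_diameters(g[c("a1", "b1", "a2", "b2", "a3", "b3")])
  for (j in 1:3) {
    sem <- cfg$diam_sd[j] / sqrt(5000)
    # truncation at 20 mm is many SDs below every configured mean
    expect_lt(abs(mean(d[, j]) - cfg$diam_mean[j]), 3 * sem)
  }
})

test_that("mean sphericity is monotone increasing in kappa", {
  cfg <- control_group_config()
  kappas <- c(1, 3, 10, 40, 150)
  means <- sapply(kappas, function(k) {
    cfg$kappa <- k
    g <- generate_group(cfg, seed = 55, n = 3000)
    mean(sphericity(g[c("a1", "b1", "a2", "b2", "a3", "b3")]))
  })
  expect_true(all(diff(means) > 0))
})

test_that("kappa calibration hits reachable targets and rejects impossible ones", {
  cfg <- control_group_config()
  cal <- calibrate_kappa(cfg, target = 72, seed = 31, n_eval = 4000, tol = 0.3)
  expect_lte(abs(cal$achieved_mean - 72), 0.3)
  expect_gt(cal$kappa, 0.5)
  # a perfect sphere is unreachable with unequal axis means
  expect_error(calibrate_kappa(cfg, target = 100, seed = 31, n_eval = 2000),
               "achievable interval")
})

test_that("the study cohort has the reference group structure", {
  cohort <- generate_study_cohort(seed = 6)
  expect_equal(as.integer(table(cohort$group)[c("control", "stroke")]),
               c(83L, 74L))
  expect_identical(cohort, generate_study_cohort(seed = 6))
  # every record passes geometry and profile validation
  expect_silent(as_radii(cohort, check_windows = TRUE))
  expect_silent(cha2ds2_vasc(cohort))
  expect_silent(has_bled(cohort))
})

test_that("calibrated cohorts show the expected group sphericity difference", {
  # at the calibrated concentrations, a two-group Welch test on simulated
  # sphericity rejects in the majority of replicate cohorts
  rejections <- 0L
  for (seed in 1:10) {
    cohort <- generate_study_cohort(seed = seed)
    lasp <- sphericity(cohort)
    p <- welch_t_raw(lasp[cohort$group == "stroke"],
                     lasp[cohort$group == "control"])$p_value
    rejections <- rejections + (p <= 0.05)
  }
  expect_gt(rejections, 5)
})

test_that("cohort CSV round-trips losslessly and validates its schema", {
  cohort <- generate_study_cohort(seed = 2)
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back, cohort, ignore_attr = TRUE)
  expect_identical(back$a1, cohort$a1) # full precision

  # unknown extra column: warning, not error
  extra <- cohort
  extra$site <- "A"
  path2 <- tempfile(fileext = ".csv")
  write_cohort(extra, path2)
  expect_warning(read_cohort(path2), "unknown column")

  # missing required column: schema error
  broken <- cohort[setdiff(names(cohort), "a2")]
  expect_error(write_cohort(broken, tempfile()), "a2")
  path3 <- tempfile(fileext = ".csv")
  write_cohort(cohort, path3)
  txt <- readLines(path3)
  txt[2] <- sub("^id,group", "id,grp", txt[2]) # damage the header
  writeLines(txt, path3)
  expect_error(read_cohort(path3), "group")
  expect_error(read_cohort(tempfile()), "no such cohort file")
})
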