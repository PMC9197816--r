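# Seeded synthetic case-control cohort generator. Each patient's three
# principal-axis diameters are drawn from truncated Gaussians; each diameter
# is split into its two center-of-mass radii by a symmetric Beta(kappa,
# kappa) fraction truncated to (0.15, 0.85), so kappa controls how equal the
# within-axis radii are and therefore how spherical the simulated atrium is.
# Clinical covariates are independent Bernoullis at configured prevalences
# (only marginal prevalences are available from case-control summary
# tables), age and appendage volume are truncated Gaussians, and appendage
# morphology is categorical over the four standard classes (1 chicken wing,
# 2 windsock, 3 cauliflower, 4 cactus).

PREVALENCE_FIELDS <- c(
  "hypertension", "diabetes", "chf", "vascular_disease",
  "renal_disease", "liver_disease", "bleeding_history", "labile_inr",
  "alcohol_use", "nsaid_or_antiplatelet",
  "on_oac", "proper_anticoagulation", "on_raas_inhibitor",
  "on_antiarrhythmic", "on_beta_blocker"
)

COHORT_SCHEMA <- c(
  "id", "group", "age", "sex", "prior_stroke_tia", PREVALENCE_FIELDS,
  "a1", "b1", "a2", "b2", "a3", "b3", "laa_volume_cm3", "laa_morphology"
)

COHORT_SCHEMA_VERSION <- "lashape-cohort-v1"

#' Configuration of one synthetic patient group
#'
#' Bundles the distributional parameters for one arm of a synthetic
#' case-control cohort: group size, the mean/SD of the three principal-axis
#' diameters (mm), the sphericity target, the Beta split concentration
#' `kappa` (calibratable via [calibrate_kappa()]), appendage volume (cm^3),
#' age (years), the prevalence of each binary covariate, and the appendage
#' morphology class probabilities.
#'
#' @param n group size.
#' @param diam_mean,diam_sd length-3 numeric: transverse, superior-inferior,
#'   anteroposterior diameter means and SDs in mm.
#' @param lasp_target target mean sphericity (percent) used by
#'   [calibrate_kappa()]; `NA` to skip calibration.
#' @param kappa Beta split concentration (> 0), or `NA` if to be calibrated.
#' @param laa_mean,laa_sd appendage volume mean/SD (cm^3), truncated > 1.
#' @param age_mean,age_sd age mean/SD (years), truncated to \[18, 120\].
#' @param p_male probability of male sex.
#' @param prevalence named list/vector of Bernoulli prevalences; names must
#'   be a subset of the cohort's binary covariates, unnamed ones default
#'   to 0.
#' @param morphology_probs length-4 probabilities for morphology classes
#'   1-4; rescaled to sum to 1.
#' @param label group label stored in the cohort (`"control"`/`"stroke"`).
#' @return a list of class `"group_config"`.
#' @export
group_config <- function(n, diam_mean, diam_sd, lasp_target = NA,
                         kappa = NA, laa_mean, laa_sd, age_mean, age_sd,
                         p_male, prevalence = list(),
                         morphology_probs = rep(0.25, 4),
                         label = "group") {
  stopifnot(length(diam_mean) == 3L, length(diam_sd) == 3L,
            all(diam_sd >= 0), all(diam_mean > 0),
            length(morphology_probs) == 4L, all(morphology_probs >= 0),
            sum(morphology_probs) > 0,
            p_male >= 0, p_male <= 1, laa_sd >= 0, age_sd >= 0)
  prev <- stats::setNames(rep(0, length(PREVALENCE_FIELDS)), PREVALENCE_FIELDS)
  if (length(prevalence)) {
    bad <- setdiff(names(prevalence), PREVALENCE_FIELDS)
    if (length(bad)) {
      stop("unknown prevalence field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    pv <- unlist(prevalence)
    if (any(pv < 0 | pv > 1)) stop("prevalences must be in [0, 1]", call. = FALSE)
    prev[names(prevalence)] <- pv
  }
  structure(
    list(
      n = as.integer(n), diam_mean = diam_mean, diam_sd = diam_sd,
      lasp_target = lasp_target, kappa = kappa,
      laa_mean = laa_mean, laa_sd = laa_sd,
      age_mean = age_mean, age_sd = age_sd, p_male = p_male,
      prevalence = prev,
      morphology_probs = morphology_probs / sum(morphology_probs),
      label = label
    ),
    class = "group_config"
  )
}

#' Built-in group configurations for the reference case-control structure
#'
#' Encodes the published two-group summary structure of a 157-patient
#' atrial-fibrillation case-control study: an 83-patient control arm and a
#' 74-patient prior-stroke arm with their reported diameter, sphericity,
#' appendage-volume, age, comorbidity, medication and morphology summaries.
#' Prevalences not reported in the source table (vascular disease and the
#' bleeding-risk components other than hypertension and age) are set to
#' modest values plausible for an elderly AF population.
#'
#' @return a `group_config`.
#' @export
control_group_config <- function() {
  group_config(
    n = 83,
    diam_mean = c(72.4, 60.11, 42.72), diam_sd = c(6.4, 6.37, 7.23),
    lasp_target = 70.54,
    laa_mean = 10.02, laa_sd = 4.52,
    age_mean = 61.4, age_sd = 10.1, p_male = 0.699,
    prevalence = list(
      hypertension = 0.446, diabetes = 0.0595, chf = 0.084,
      vascular_disease = 0.10,
      renal_disease = 0.05, liver_disease = 0.02, bleeding_history = 0.05,
      labile_inr = 0.15, alcohol_use = 0.05, nsaid_or_antiplatelet = 0.15,
      on_oac = 0.9157, proper_anticoagulation = 0.8675,
      on_raas_inhibitor = 0.5904, on_antiarrhythmic = 0.5904,
      on_beta_blocker = 0.6627
    ),
    morphology_probs = c(0.325, 0.289, 0.169, 0.217),
    label = "control"
  )
}

#' @rdname control_group_config
#' @export
stroke_group_config <- function() {
  group_config(
    n = 74,
    diam_mean = c(77.04, 59.38, 47.47), diam_sd = c(10.4, 10.41, 11.03),
    lasp_target = 66.58,
    laa_mean = 12.2, laa_sd = 7.57,
    age_mean = 71.4, age_sd = 11.0, p_male = 0.554,
    prevalence = list(
      hypertension = 0.878, diabetes = 0.2469, chf = 0.419,
      vascular_disease = 0.20,
      renal_disease = 0.10, liver_disease = 0.03, bleeding_history = 0.10,
      labile_inr = 0.20, alcohol_use = 0.08, nsaid_or_antiplatelet = 0.20,
      on_oac = 0.3108, proper_anticoagulation = 0.1351,
      on_raas_inhibitor = 0.6216, on_antiarrhythmic = 0.0541,
      on_beta_blocker = 0.527
    ),
    morphology_probs = c(0.391, 0.122, 0.135, 0.311),
    label = "stroke"
  )
}

# geometry-only draw: diameters + Beta splits -> n x 6 radius matrix.
# Assumes the RNG state is already set by the caller.
draw_radii <- function(n, cfg, kappa) {
  d1 <- rtruncnorm(n, cfg$diam_mean[1], cfg$diam_sd[1], lower = 20)
  d2 <- rtruncnorm(n, cfg$diam_mean[2], cfg$diam_sd[2], lower = 20)
  d3 <- rtruncnorm(n, cfg$diam_mean[3], cfg$diam_sd[3], lower = 20)
  f1 <- rtruncbeta_sym(n, kappa)
  f2 <- rtruncbeta_sym(n, kappa)
  f3 <- rtruncbeta_sym(n, kappa)
  cbind(
    a1 = f1 * d1, b1 = (1 - f1) * d1,
    a2 = f2 * d2, b2 = (1 - f2) * d2,
    a3 = f3 * d3, b3 = (1 - f3) * d3
  )
}

#' Generate one synthetic patient group
#'
#' Draws `n` (or `cfg$n`) patients from the group's configured
#' distributions. Deterministic given `(cfg, seed)`: each component
#' (geometry, demographics, comorbidities, medications, morphology) draws
#' from its own sub-stream derived via [derive_seed()], so any component can
#' be regenerated independently.
#'
#' @param cfg a [group_config()]; `cfg$kappa` must be set (see
#'   [calibrate_kappa()]).
#' @param seed integer seed.
#' @param n optional override of `cfg$n`.
#' @return a data frame with the cohort schema columns (see
#'   [read_cohort()]); `prior_stroke_tia` is `FALSE` for all rows (the
#'   stroke-arm event is the index event, not a pre-existing history).
#' @export
generate_group <- function(cfg, seed, n = cfg$n) {
  stopifnot(inherits(cfg, "group_config"))
  if (!is.finite(cfg$kappa) || cfg$kappa <= 0) {
    stop("`cfg$kappa` is not set; run calibrate_kappa() or supply one",
         call. = FALSE)
  }
  radii <- local_seed(derive_seed(seed, paste0(cfg$label, ":geometry")),
                      draw_radii(n, cfg, cfg$kappa))
  demo <- local_seed(derive_seed(seed, paste0(cfg$label, ":demographics")), {
    list(
      age = rtruncnorm(n, cfg$age_mean, cfg$age_sd, lower = 18, upper = 120),
      sex = ifelse(stats::runif(n) < cfg$p_male, "male", "female"),
      laa = rtruncnorm(n, cfg$laa_mean, cfg$laa_sd, lower = 1)
    )
  })
  comorb <- local_seed(derive_seed(seed, paste0(cfg$label, ":covariates")), {
    out <- lapply(cfg$prevalence, function(p) stats::runif(n) < p)
    names(out) <- names(cfg$prevalence)
    out
  })
  morph <- local_seed(derive_seed(seed, paste0(cfg$label, ":morphology")),
                      sample.int(4L, n, replace = TRUE,
                                 prob = cfg$morphology_probs))
  out <- data.frame(
    id = paste0(cfg$label, "_", seq_len(n)),
    group = cfg$label,
    age = demo$age,
    sex = demo$sex,
    prior_stroke_tia = rep(FALSE, n)
  )
  out <- cbind(out, as.data.frame(comorb))
  out <- cbind(out, as.data.frame(radii))
  out$laa_volume_cm3 <- demo$laa
  out$laa_morphology <- morph
  out[COHORT_SCHEMA]
}

# mean simulated sphericity at a given kappa (geometry only, own stream)
simulated_lasp_mean <- function(cfg, kappa, seed, n_eval,
                                sd_mode = "sample") {
  radii <- local_seed(seed, draw_radii(n_eval, cfg, kappa))
  mean(sphericity(radii, sd_mode))
}

#' Calibrate the Beta split concentration against a sphericity target
#'
#' Mean simulated sphericity is monotone increasing in `kappa` (larger
#' concentration pushes the split fractions toward 1/2, equalizing the
#' within-axis radii), so a bisection on `kappa` against the simulated mean
#' solves for the configured target. Each evaluation simulates `n_eval`
#' patients under common random numbers (the same sub-seed), making the
#' bisection function smooth and strictly monotone.
#'
#' @param cfg a [group_config()].
#' @param target target mean sphericity in percent; defaults to
#'   `cfg$lasp_target`.
#' @param seed integer seed for the calibration draws (one shared stream
#'   across evaluations).
#' @param n_eval patients per evaluation.
#' @param tol stop once the achieved mean is within `tol` of the target.
#' @param kappa_range search interval for `kappa`.
#' @param max_iter bisection iteration cap.
#' @param sd_mode SD convention passed to [sphericity()].
#' @return a list: `kappa`, `achieved_mean`, `iterations`.
#' @export
calibrate_kappa <- function(cfg, target = cfg$lasp_target, seed = 42,
                            n_eval = 20000, tol = 0.25,
                            kappa_range = c(0.5, 500), max_iter = 60,
                            sd_mode = "sample") {
  stopifnot(inherits(cfg, "group_config"))
  if (!is.finite(target)) stop("no sphericity target supplied", call. = FALSE)
  eval_seed <- derive_seed(seed, paste0(cfg$label, ":calibration"))
  f <- function(k) simulated_lasp_mean(cfg, k, eval_seed, n_eval, sd_mode)
  lo <- kappa_range[1]; hi <- kappa_range[2]
  flo <- f(lo); fhi <- f(hi)
  if (target < flo - tol || target > fhi + tol) {
    stop(sprintf(
      "sphericity target %.2f outside the achievable interval [%.2f, %.2f] for kappa in [%g, %g]",
      target, flo, fhi, lo, hi
    ), call. = FALSE)
  }
  it <- 0L
  mid <- (lo + hi) / 2
  fmid <- f(mid)
  while (abs(fmid - target) > tol && it < max_iter) {
    if (fmid < target) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
    fmid <- f(mid)
    it <- it + 1L
  }
  if (abs(fmid - target) > tol) {
    stop("kappa bisection failed to reach the target within tolerance",
         call. = FALSE)
  }
  list(kappa = mid, achieved_mean = fmid, iterations = it)
}

# per-session cache so repeated study-cohort generation calibrates once
.calibration_cache <- new.env(parent = emptyenv())

#' Set a group's kappa by calibration (cached)
#'
#' @inheritParams calibrate_kappa
#' @return `cfg` with `kappa` filled in.
#' @export
calibrated_config <- function(cfg, seed = 42, ...) {
  key <- paste(cfg$label, paste(cfg$diam_mean, collapse = ","),
               paste(cfg$diam_sd, collapse = ","), cfg$lasp_target, seed,
               sep = "|")
  if (!is.null(.calibration_cache[[key]])) {
    cfg$kappa <- .calibration_cache[[key]]
    return(cfg)
  }
  cal <- calibrate_kappa(cfg, seed = seed, ...)
  .calibration_cache[[key]] <- cal$kappa
  cfg$kappa <- cal$kappa
  cfg
}

#' Generate the full synthetic study cohort
#'
#' Concatenates an 83-patient control arm and a 74-patient stroke arm drawn
#' from the built-in configurations ([control_group_config()],
#' [stroke_group_config()]) with `kappa` calibrated per group against each
#' arm's sphericity target (calibration uses its own fixed stream, so the
#' cohort seed only drives the patient draws).
#'
#' @param seed integer seed for the patient draws.
#' @param calibration_seed seed of the calibration stream.
#' @return a data frame of 157 patients with attributes `schema_version`
#'   and `seed`; the stroke arm is the case group (`group == "stroke"`).
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_study_cohort(seed = 1)
#' table(cohort$group)
#' }
generate_study_cohort <- function(seed, calibration_seed = 42) {
  ctrl <- calibrated_config(control_group_config(), seed = calibration_seed)
  strk <- calibrated_config(stroke_group_config(), seed = calibration_seed)
  cohort <- rbind(
    generate_group(ctrl, seed),
    generate_group(strk, seed)
  )
  rownames(cohort) <- NULL
  attr(cohort, "schema_version") <- COHORT_SCHEMA_VERSION
  attr(cohort, "seed") <- seed
  cohort
}

#' Write / read a cohort CSV
#'
#' The CSV round-trip is lossless: numeric fields are written with 17
#' significant digits. The first line is a comment carrying the schema
#' version. Unknown extra columns are kept with a warning; a missing
#' required column is an error.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `read_cohort` returns the cohort data frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing <- setdiff(COHORT_SCHEMA, names(cohort))
  if (length(missing)) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- cohort
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", COHORT_SCHEMA_VERSION), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#") || !grepl("lashape-cohort", first)) {
    warning("cohort file has no schema header; attempting to parse anyway",
            call. = FALSE)
  }
  cohort <- utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  missing <- setdiff(COHORT_SCHEMA, names(cohort))
  if (length(missing)) {
    stop("cohort file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(cohort), COHORT_SCHEMA)
  if (length(extra)) {
    warning("unknown column(s) retained: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  logicals <- c("prior_stroke_tia", PREVALENCE_FIELDS)
  cohort[logicals] <- lapply(cohort[logicals], as.logical)
  attr(cohort, "schema_version") <- sub("^#\\s*", "", first)
  cohort
}
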