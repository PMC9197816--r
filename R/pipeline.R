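# End-to-end analysis pipeline: from a cohort table to a machine-readable
# report mirroring the tables and ROC figures of a case-control LA-shape
# study: group comparison table, univariate odds ratios, one multivariate
# logistic model, sphericity/discriminant/clinical-score ROC curves,
# sphericity tertiles, and the LOOCV misclassification of the re-fitted
# discriminant.

CONTINUOUS_VARS <- c(
  "age", "d_transverse", "d_supinf", "d_anteropost",
  "laa_volume_cm3", "lasp", "la_volume_cm3", "cha2ds2_vasc", "has_bled"
)
BINARY_VARS <- c(
  "male", "hypertension", "diabetes", "chf",
  "on_raas_inhibitor", "on_oac", "proper_anticoagulation",
  "on_antiarrhythmic", "on_beta_blocker"
)
OR_VARS <- c(
  "male", "diabetes", "hypertension", "chf", "cha2ds2_vasc",
  "la_volume_cm3", "d_transverse", "d_supinf", "d_anteropost",
  "laa_volume_cm3", "laa_non_cw", "lasp"
)

#' Pipeline configuration
#'
#' All analysis-level switches in one serializable object.
#'
#' @param sd_mode SD convention for sphericity: `"sample"` or
#'   `"population"`.
#' @param test_mode `"welch"` (Welch everywhere, default) or `"gated"`
#'   (pooled Student's t when both groups pass Shapiro-Wilk at alpha =
#'   0.05, Welch otherwise).
#' @param chisq_correct Yates continuity correction for 2x2 chi-square.
#' @param priors discriminant priors: `"empirical"` or `"equal"`.
#' @param threshold_mode which LOOCV PIC to headline: `"bayes"` (per-fold
#'   Bayes rule) or `"optimized"` (post-hoc common cutoff).
#' @param flip_lasp report the sphericity ROC in the flipped
#'   (lower-riskier) orientation instead of raw.
#' @param conf_level confidence level for AUC intervals.
#' @param case_label value of the cohort `group` column marking cases.
#' @param seed seed echoed into the report (the analysis itself is
#'   deterministic given the cohort).
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sd_mode = "sample", test_mode = "welch",
                            chisq_correct = FALSE, priors = "empirical",
                            threshold_mode = "bayes", flip_lasp = FALSE,
                            conf_level = 0.95, case_label = "stroke",
                            seed = 1L) {
  sd_mode <- match.arg(sd_mode, c("sample", "population"))
  test_mode <- match.arg(test_mode, c("welch", "gated"))
  priors <- match.arg(priors, c("empirical", "equal"))
  threshold_mode <- match.arg(threshold_mode, c("bayes", "optimized"))
  structure(
    list(
      sd_mode = sd_mode, test_mode = test_mode,
      chisq_correct = isTRUE(chisq_correct), priors = priors,
      threshold_mode = threshold_mode, flip_lasp = isTRUE(flip_lasp),
      conf_level = conf_level, case_label = case_label,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  writeLines(yaml::as.yaml(unclass(cfg)), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

group_test <- function(x1, x2, test_mode) {
  if (test_mode == "gated" &&
      stats::shapiro.test(x1)$p.value > 0.05 &&
      stats::shapiro.test(x2)$p.value > 0.05) {
    student_t_pooled(summarize_sample(x1), summarize_sample(x2))
  } else {
    welch_t_raw(x1, x2)
  }
}

median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.1f [%.1f-%.1f]", q[2], q[1], q[3])
}

#' Run the full analysis on a cohort
#'
#' Computes shape metrics and clinical scores per patient and produces the
#' complete statistical report. The stroke-history component of HAS-BLED
#' counts case status (the index event), while CHA2DS2-VASc uses the
#' pre-event history column, matching a design where the clinical score is
#' the one that applied before the event.
#'
#' @param cohort cohort data frame (schema of [read_cohort()]).
#' @param config a [pipeline_config()].
#' @return a list of class `"la_analysis_report"` with elements
#'   `table1` (per-variable group summaries and tests), `univariate_or`
#'   and `multivariate` (odds-ratio tables), `lasp_roc`,
#'   `discriminant`, `clinical_combination`, `tertiles`, `meta`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_analysis(generate_study_cohort(1))
#' rep$discriminant$loocv_pic
#' }
run_analysis <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  required <- c("group", "age", "sex", COHORT_SCHEMA[
    !COHORT_SCHEMA %in% c("id", "laa_morphology")])
  missing <- setdiff(unique(required), names(cohort))
  if (length(missing)) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  y <- as.integer(cohort$group == config$case_label)
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop(sprintf("cohort must contain both cases (group == \"%s\") and controls",
                 config$case_label), call. = FALSE)
  }

  enriched <- add_shape_metrics(cohort, sd_mode = config$sd_mode)
  enriched$male <- enriched$sex == "male"
  enriched$cha2ds2_vasc <- cha2ds2_vasc(enriched)
  enriched$has_bled <- has_bled(enriched,
                                stroke = (y == 1) | enriched$prior_stroke_tia)
  enriched$laa_non_cw <- if ("laa_morphology" %in% names(enriched)) {
    enriched$laa_morphology != 1L
  } else {
    NA
  }

  ## -- group-comparison table ------------------------------------------------
  is_case <- y == 1
  cont_rows <- lapply(CONTINUOUS_VARS, function(v) {
    x0 <- enriched[[v]][!is_case]
    x1 <- enriched[[v]][is_case]
    tt <- group_test(x1, x0, config$test_mode)
    data.frame(
      variable = v, type = "continuous",
      control = sprintf("%.2f ± %.2f", mean(x0), stats::sd(x0)),
      stroke = sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1)),
      control_median = median_iqr(x0), stroke_median = median_iqr(x1),
      control_mean = mean(x0), control_sd = stats::sd(x0),
      stroke_mean = mean(x1), stroke_sd = stats::sd(x1),
      method = tt$method, p_value = tt$p_value
    )
  })
  bin_rows <- lapply(BINARY_VARS, function(v) {
    x <- as.integer(enriched[[v]])
    tab <- rbind(c(sum(x[is_case]), sum(1 - x[is_case])),
                 c(sum(x[!is_case]), sum(1 - x[!is_case])))
    tt <- chi_square_or_fisher(tab, correct = config$chisq_correct)
    data.frame(
      variable = v, type = "binary",
      control = sprintf("%.1f%%", 100 * mean(x[!is_case])),
      stroke = sprintf("%.1f%%", 100 * mean(x[is_case])),
      control_median = NA_character_, stroke_median = NA_character_,
      control_mean = mean(x[!is_case]), control_sd = NA_real_,
      stroke_mean = mean(x[is_case]), stroke_sd = NA_real_,
      method = tt$method, p_value = tt$p_value
    )
  })
  table1 <- do.call(rbind, c(cont_rows, bin_rows))
  morph_test <- if (all(!is.na(enriched$laa_non_cw))) {
    tab <- table(factor(y, levels = c(1, 0)),
                 factor(enriched$laa_morphology, levels = 1:4))
    chi_square_or_fisher(as.matrix(tab), correct = config$chisq_correct)
  } else {
    NULL
  }

  ## -- odds ratios -----------------------------------------------------------
  uni <- do.call(rbind, lapply(OR_VARS, function(v) {
    fit <- logistic_fit(stats::setNames(enriched[v], v), y)
    row <- fit$table[fit$table$term != "(Intercept)", , drop = FALSE]
    row$term <- v
    row
  }))
  multi <- logistic_fit(enriched[OR_VARS], y)

  ## -- ROC / discriminant ----------------------------------------------------
  lasp_roc <- roc_curve(
    enriched$lasp, y,
    direction = if (config$flip_lasp) "lower_riskier" else "higher_riskier",
    conf_level = config$conf_level
  )
  features <- discriminant_features(enriched, sd_mode = config$sd_mode)
  lda <- fit_lda(features, y, priors = config$priors)
  loocv <- loocv_pic(features, y, priors = config$priors)
  disc_roc <- roc_curve(loocv$posterior, y, conf_level = config$conf_level)
  cutoff <- youden_optimal_cutoff(disc_roc)
  combo <- combine_with_clinical(loocv$scores, enriched$cha2ds2_vasc, y)
  tert <- tertile_analysis(enriched$lasp, y)

  structure(
    list(
      table1 = table1,
      morphology_test = morph_test,
      univariate_or = uni,
      multivariate = multi,
      lasp_roc = lasp_roc,
      discriminant = list(
        fit = lda,
        loocv_pic = if (config$threshold_mode == "bayes") loocv$pic else loocv$pic_optimized,
        loocv_pic_bayes = loocv$pic,
        loocv_pic_optimized = loocv$pic_optimized,
        loocv = loocv,
        roc = disc_roc,
        youden = cutoff,
        published_scores = published_score(as.data.frame(features))
      ),
      clinical_combination = combo,
      tertiles = tert,
      meta = list(
        n = length(y), n_cases = sum(y), n_controls = sum(1 - y),
        config = unclass(config),
        package_version = as.character(utils::packageVersion("lashape"))
      )
    ),
    class = "la_analysis_report"
  )
}

#' @export
print.la_analysis_report <- function(x, ...) {
  cat(sprintf(
    "LA shape analysis report: %d patients (%d cases / %d controls)\n",
    x$meta$n, x$meta$n_cases, x$meta$n_controls
  ))
  cat(sprintf("  sphericity ROC AUC (raw): %.4f\n", x$lasp_roc$auc))
  cat(sprintf("  discriminant LOOCV AUC:   %.4f  PIC: %.4f\n",
              x$discriminant$roc$auc, x$discriminant$loocv_pic))
  cat(sprintf("  CHA2DS2-VASc AUC: %.4f  + discriminant: %.4f\n",
              x$clinical_combination$auc_alone,
              x$clinical_combination$auc_combined))
  cat(sprintf("  sphericity tertile case %%: %s (chi-square p = %.4f)\n",
              paste(sprintf("%.1f", x$tertiles$percent_cases), collapse = " / "),
              x$tertiles$test$p_value))
  invisible(x)
}

# recursively strip S3 classes / glm objects down to JSON-friendly lists
report_to_plain <- function(x) {
  if (inherits(x, "logistic_fit")) {
    return(list(
      table = x$table, converged = x$converged,
      n_iterations = x$n_iterations, separation_flag = x$separation_flag,
      loglik = x$loglik, n = x$n
    ))
  }
  if (inherits(x, "lda_fit")) {
    x <- unclass(x)
    x$pooled_cov <- NULL
    x$class_means <- NULL
    x$coefficients <- as.list(x$coefficients)
    x$means <- unname(x$means)
    return(lapply(x, report_to_plain))
  }
  if (inherits(x, "loocv_pic")) {
    x <- unclass(x)
    x$labels <- as.character(x$labels)
    x$predicted <- as.character(x$predicted)
    return(lapply(x, report_to_plain))
  }
  if (is.data.frame(x)) return(x)
  if (inherits(x, c("roc_curve_fit", "two_group_test"))) x <- unclass(x)
  if (is.list(x)) return(lapply(x, report_to_plain))
  if (is.matrix(x)) return(as.data.frame(x))
  if (is.factor(x)) return(as.character(x))
  if (!is.null(names(x)) && length(x) > 1L) return(as.list(x))
  x
}

#' Render an analysis report to disk
#'
#' `"json"` writes one deterministic JSON file (full precision);
#' `"csv"` writes a bundle of CSV tables (group comparisons, odds-ratio
#' tables, ROC operating points, headline numbers); `"markdown"` writes a
#' single human-readable document containing every table.
#'
#' @param report a [run_analysis()] result.
#' @param path output file (json/markdown) or directory (csv bundle).
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return the path(s) written, invisibly.
#' @export
render_report <- function(report, path, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "la_analysis_report"))
  plain <- report_to_plain(report)
  if (format == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      table1 = file.path(path, "table1.csv"),
      univariate = file.path(path, "univariate_or.csv"),
      multivariate = file.path(path, "multivariate_or.csv"),
      lasp_roc = file.path(path, "roc_lasp.csv"),
      disc_roc = file.path(path, "roc_discriminant.csv"),
      clin_roc = file.path(path, "roc_clinical.csv"),
      comb_roc = file.path(path, "roc_combined.csv"),
      summary = file.path(path, "summary.csv")
    )
    utils::write.csv(report$table1, files["table1"], row.names = FALSE)
    utils::write.csv(report$univariate_or, files["univariate"], row.names = FALSE)
    utils::write.csv(report$multivariate$table, files["multivariate"], row.names = FALSE)
    utils::write.csv(report$lasp_roc$points, files["lasp_roc"], row.names = FALSE)
    utils::write.csv(report$discriminant$roc$points, files["disc_roc"], row.names = FALSE)
    utils::write.csv(report$clinical_combination$roc_alone$points,
                     files["clin_roc"], row.names = FALSE)
    utils::write.csv(report$clinical_combination$roc_combined$points,
                     files["comb_roc"], row.names = FALSE)
    headline <- data.frame(
      quantity = c("lasp_auc_raw", "discriminant_auc", "loocv_pic",
                   "clinical_auc", "combined_auc", "tertile1_pct",
                   "tertile2_pct", "tertile3_pct", "tertile_p"),
      value = c(report$lasp_roc$auc, report$discriminant$roc$auc,
                report$discriminant$loocv_pic,
                report$clinical_combination$auc_alone,
                report$clinical_combination$auc_combined,
                report$tertiles$percent_cases, report$tertiles$test$p_value)
    )
    utils::write.csv(headline, files["summary"], row.names = FALSE)
    return(invisible(files))
  }
  # markdown
  md <- c(
    "# LA shape analysis report", "",
    sprintf("%d patients: %d cases / %d controls.",
            report$meta$n, report$meta$n_cases, report$meta$n_controls), "",
    "## Group comparisons", "", df_to_md(report$table1[
      c("variable", "control", "stroke", "method", "p_value")]), "",
    "## Univariate odds ratios", "", df_to_md(report$univariate_or), "",
    "## Multivariate model", "", df_to_md(report$multivariate$table), "",
    "## Discrimination", "",
    sprintf("- Sphericity ROC AUC (raw orientation): %.4f [%.4f-%.4f]",
            report$lasp_roc$auc, report$lasp_roc$ci_low, report$lasp_roc$ci_high),
    sprintf("- Discriminant LOOCV ROC AUC: %.4f [%.4f-%.4f], PIC %.4f",
            report$discriminant$roc$auc, report$discriminant$roc$ci_low,
            report$discriminant$roc$ci_high, report$discriminant$loocv_pic),
    sprintf("- CHA2DS2-VASc AUC %.4f; with discriminant %.4f",
            report$clinical_combination$auc_alone,
            report$clinical_combination$auc_combined),
    sprintf("- Sphericity tertile case %%: %s (p = %.4f)",
            paste(sprintf("%.1f", report$tertiles$percent_cases), collapse = " / "),
            report$tertiles$test$p_value)
  )
  writeLines(md, path)
  invisible(path)
}

df_to_md <- function(df) {
  df[] <- lapply(df, function(x) {
    if (is.numeric(x)) signif(x, 4) else x
  })
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Read back a JSON report
#'
#' @param path a JSON file written by [render_report()].
#' @return the plain-list form of the report.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
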