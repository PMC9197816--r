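# lashape

Left atrial (LA) shape statistics and discriminant stroke-risk analysis for
atrial fibrillation (AF) case-control cohorts.

## The problem

Stroke risk in AF is conventionally stratified with the CHA₂DS₂-VASc score,
which discriminates only moderately. The shape of the left atrium carries
additional signal: structural remodeling distorts the chamber away from a
sphere, and that distortion is measurable on cardiac CT with nothing more
than six radii — the distances from the LA center of mass to the wall along
the three principal axes (A₁, B₁ transverse; A₂, B₂ superior–inferior; A₃,
B₃ anteroposterior, in mm).

From these six numbers the package computes the standard shape statistics

- **AR** = mean(A₁, B₁, A₂, B₂, A₃, B₃), the best-fitting-sphere radius;
- **LASP** (sphericity) = (1 − SDR/AR) × 100, where SDR is the SD of the six
  radii — 100% is a perfect sphere, and the statistic is scale-invariant;
- **VC** (volume coefficient) = Σ rᵢ³, with (2π/9)·VC equal to the mean
  volume of the six radius-matched spheres;

and implements the linear discriminant built on them,

```
score = 0.0161·A1 − 0.0192·A2 + 0.1076·A3 − 0.0016·B1 − 0.0694·B2
        + 0.1321·B3 − 0.1102·LASP + 0.0061·VC/10⁴ ,
```

whose published operating threshold (−0.0863) ships as
`la_discriminant_threshold`. The package is for biostatisticians and
imaging researchers who want to apply this score to their own cohorts, re-fit
it with leave-one-out cross-validated (LOOCV) misclassification estimates, or
audit published summary-level results.

Around that core sit the supporting analyses such studies report: Welch and
pooled t-tests computable from printed (n, mean, SD) summaries as well as raw
data, chi-square/Fisher tests, Pearson collinearity checks, univariate and
multivariate logistic odds-ratio tables, empirical ROC curves with DeLong
confidence intervals, Youden-optimal cutoffs, tertile analyses, CHA₂DS₂-VASc
and HAS-BLED scoring, combination of the discriminant with a clinical score,
and a seeded synthetic cohort generator calibrated so that simulated
sphericity matches configured group targets.

## Worked example

Shape metrics for one patient's radii (mm):

```r
library(lashape)
shape_metrics(c(a1 = 40, b1 = 32, a2 = 35, b2 = 29, a3 = 27, b3 = 23))
#>   ar      sdr       cvs     lasp     vc d_transverse d_supinf d_anteropost
#> 1 31 6.033241 0.1946207 80.53793 195882           72       64           50
```

The mean radius is 31 mm, the three diameters 72/64/50 mm, and the
dispersion of the radii puts sphericity at 80.5% — a fairly symmetric
atrium. `vc = 195882` mm³ corresponds to (2π/9)·VC ≈ 137 cm³ of estimated
LA volume.

A published group comparison can be checked from its printed summaries
alone. For sphericity 70.54 ± 6.95 in 83 controls versus 66.58 ± 10.34 in
74 cases:

```r
welch_t_from_summary(group_summary(83, 70.54, 6.95),
                     group_summary(74, 66.58, 10.34))
#> Welch two-sample t-test (from summaries)
#>   statistic = 2.78159 , df = 125.522 , p = 0.006244
```

The full pipeline on a synthetic 157-patient cohort (83 controls, 74
prior-stroke cases, geometry calibrated to those group sphericities):

```r
cohort <- generate_study_cohort(seed = 1)
report <- run_analysis(cohort)
report
#> LA shape analysis report: 157 patients (74 cases / 83 controls)
#>   sphericity ROC AUC (raw): 0.2789
#>   discriminant LOOCV AUC:   0.7966  PIC: 0.2675
#>   CHA2DS2-VASc AUC: 0.9118  + discriminant: 0.9459
#>   sphericity tertile case %: 73.1 / 40.4 / 28.3 (chi-square p = 0.0000)
```

Reading the output: raw sphericity, being *lower* in cases, gives a
raw-orientation AUC below 0.5 (0.28); the re-fitted eight-feature
discriminant separates far better (LOOCV AUC 0.80, misclassifying 27% of
held-out patients); and adding it to CHA₂DS₂-VASc raises the clinical
score's AUC from 0.91 to 0.95. Cases concentrate in the lowest sphericity
tertile (73% vs 28% in the highest). `render_report(report, "report.json",
"json")` serializes every table and ROC curve; `report$multivariate$table`
holds the odds-ratio table.

A command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/lashape-cli.R", package="lashape"))') \
    simulate --seed 1 --out cohort.csv
# ... analyze --in cohort.csv --out report.json
# ... score   --in cohort.csv --out scores.csv --threshold -0.0863
```

## Package layout

| Area | Functions |
|---|---|
| Geometry | `as_radii`, `average_radius`, `sphericity`, `volume_coefficient`, `derive_diameters`, `shape_metrics`, `add_shape_metrics` |
| Clinical scores | `cha2ds2_vasc`, `has_bled` |
| Statistics | `welch_t_from_summary`, `welch_t_raw`, `student_t_pooled`, `chi_square_or_fisher`, `pearson_correlation`, `logistic_fit`, `roc_curve`, `youden_optimal_cutoff`, `tertile_analysis` |
| Discriminant | `published_score`, `discriminant_features`, `fit_lda`, `posterior_probability`, `classify_lda`, `loocv_pic`, `canonical_variates`, `combine_with_clinical` |
| Synthetic cohorts | `group_config`, `control_group_config`, `stroke_group_config`, `generate_group`, `calibrate_kappa`, `generate_study_cohort`, `write_cohort`, `read_cohort` |
| Pipeline | `pipeline_config`, `run_analysis`, `render_report`, `read_report` |

The methods vignette (`vignettes/la-shape-methods.Rmd`) documents the model,
the calibration scheme, what the synthetic generator does and does not
emulate, and the numerical choices.
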