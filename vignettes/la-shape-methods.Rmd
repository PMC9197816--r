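---
title: "Left atrial shape statistics and discriminant stroke-risk analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left atrial shape statistics and discriminant stroke-risk analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lashape)
```

## The measurement model

`lashape` analyzes left atrial (LA) shape from six radial measurements taken
on cardiac CT. The atrium is cut by three planes along its principal axes —
transverse, superior–inferior and anteroposterior — and each axis is split by
the LA center of mass into two radii: $A_1, B_1$ (transverse), $A_2, B_2$
(superior–inferior), $A_3, B_3$ (anteroposterior), all in millimetres. The
sums $A_i + B_i$ are the three principal-axis diameters. Everything the
package computes downstream is a function of these six numbers; no image
processing is involved, and the radii are taken as given measurements.

From the six radii the package derives:

- **Average radius** $AR = \mathrm{mean}(A_1, B_1, A_2, B_2, A_3, B_3)$ — the
  radius of the sphere best fitting the atrium.
- **Sphericity** $LASP = (1 - CVS) \times 100$ with $CVS = SDR / AR$, the
  coefficient of variation of the six radii. $LASP = 100$ exactly when all
  six radii are equal (a perfect sphere), and the statistic is invariant to
  overall scale: a large spherical atrium and a small spherical atrium score
  identically. Dilation per se does not change sphericity; *asymmetric*
  remodeling does.
- **Volume coefficient** $VC = \sum_i r_i^3$ (mm³). Its volumetric reading:
  $(2\pi/9)\,VC$ equals the mean of the volumes of the six spheres with radii
  $r_i$, since $\mathrm{mean}(\tfrac{4}{3}\pi r_i^3) = \tfrac{4\pi}{18}\sum
  r_i^3 / 1$. The pipeline reports $(2\pi/9)\,VC / 1000$ in cm³ as its LA
  volume estimate.

**The SD divisor.** Published sphericity values based on this construction do
not state whether $SDR$ uses the sample ($n-1$) or population ($n$) divisor.
The package defaults to the sample SD, the convention of essentially all
general statistical software, and exposes `sd_mode = "population"`
throughout. The two conventions differ by the fixed factor $\sqrt{5/6}$ in
$SDR$, so population-SD sphericities sit about 9% closer to 100 in relative
distance from the spherical limit; comparisons are unaffected as long as one
convention is used consistently.

**Validation windows.** Radii must be finite and strictly positive.
Anatomical plausibility checks (each diameter in 20–150 mm) are available via
`check_windows = TRUE` but off by default, so that property-style stress
tests can explore arbitrary positive radii.

## The discriminant score

The package ships the published eight-coefficient linear discriminant over
$(A_1, A_2, A_3, B_1, B_2, B_3, LASP, VC/10^4)$ as `published_score()`, with
the printed operating threshold $-0.0863$ stored as
`la_discriminant_threshold`. Two caveats are built into the documentation
rather than papered over:

- The printed function carries no explicit centering. Discriminant software
  commonly centers features at their grand means before projecting, and the
  centering convention shifts all scores (and hence the threshold) by a
  constant. Absolute score levels from `published_score()` are therefore only
  comparable to the published threshold under the same convention the
  original fit used, which cannot be recovered from the printed coefficients
  alone. Scores re-fitted on a new cohort should use that fit's own
  threshold.
- The score consumes $VC/10^4$, not $VC$; `published_score()` accepts either
  `vc_scaled` or raw `vc` and scales internally.

`fit_lda()` re-estimates the discriminant on any cohort: coefficients
proportional to $S^{-1}(\mu_2 - \mu_1)$ with $S$ the pooled within-class
covariance (divisor $n-2$), rescaled to unit pooled within-class variance of
the score, with the case class on the positive side. Posteriors follow the
equal-covariance Gaussian model, so they are a logistic function of the
score. Priors default to empirical class frequencies and can be set to equal
or to explicit values. Singular pooled covariances are an error that names
the most collinear feature pair instead of silently pseudo-inverting.

### Leave-one-out cross-validation

`loocv_pic()` estimates the probability of incorrect classification (PIC) by
refitting the discriminant $n$ times, each time classifying the held-out
subject. The default implementation downdates the class mean and pooled
scatter by a rank-one update
$W_{-i} = W - \tfrac{n_k}{n_k - 1}(x_i - \bar{x}_k)(x_i - \bar{x}_k)^\top$
rather than refitting from scratch; the two are algebraically identical, and
the test suite asserts exact equality of the error rates against a naive
refit-per-fold oracle.

Whether a published "optimal threshold" was selected inside or outside a
cross-validation loop changes the optimism of the error estimate, and is
generally not recoverable from a printed summary. Both conventions are
therefore computed: `pic` applies each fold's own Bayes rule (the threshold
never sees the prediction it gates), while `pic_optimized` sweeps a single
common cutoff over the pooled cross-validated posteriors after the fact
(ties broken toward the lower threshold). The optimized variant is never
larger, and the pipeline reports both, headlining the one chosen in
`pipeline_config(threshold_mode = )` (default: the unoptimized Bayes rule,
the less optimistic of the two).

For three or more groups, `canonical_variates()` computes Fisher canonical
coordinates by eigen-decomposition of $W^{-1}B$ through a symmetric Cholesky
reduction, scaled to unit within-class variance and with signs fixed so the
first class has non-positive mean on each variate — useful, for example, to
display controls against anticoagulated and non-anticoagulated case
subgroups in one plane.

## The statistical battery

- **Two-group tests.** `welch_t_from_summary()` computes the Welch statistic
  with Welch–Satterthwaite degrees of freedom directly from $(n, \bar{x},
  s)$ triples, so p-values printed in a publication can be checked from its
  summary table alone; `welch_t_raw()` is the same test from raw samples and
  agrees with the summary version to machine precision by construction.
  Which rows of a published table used pooled Student's t versus Welch is
  rarely stated; the pipeline defaults to Welch everywhere (valid whether or
  not variances are equal, at a small power cost) and offers a
  Shapiro–Wilk-gated mode (`test_mode = "gated"`) that falls back to the
  pooled test when both groups look Gaussian at $\alpha = 0.05$. Every
  report row labels the test actually used.
- **Categorical tests.** Pearson chi-square without continuity correction by
  default (a flag enables Yates); 2×2 tables switch to Fisher's exact test
  when any expected cell is below 5 *or any observed cell is zero* — the
  zero-cell clause covers balanced-margin degenerate tables whose expected
  counts are exactly 5 but whose chi-square approximation is poor.
- **Logistic regression.** `logistic_fit()` wraps the standard IRLS fit with
  a tight convergence tolerance, reports Wald standard errors and 95%
  intervals as $\exp(\hat\beta \pm 1.96\,SE)$, and flags non-convergence and
  quasi-separation (any |coefficient| above 15 by default) instead of
  printing implausible odds ratios silently. Quasi-separation is not
  hypothetical here: with strong clinical contrasts between arms (e.g. a
  five-fold difference in heart-failure prevalence), the multivariate model
  can produce diverging coefficients, and published univariate odds ratios
  of the order of 50 with confidence intervals spanning three decades are
  exactly the signature this flag is designed to surface.
- **ROC analysis.** `roc_curve()` builds the empirical curve over all
  distinct thresholds and computes the AUC as the Mann–Whitney probability
  of correct ordering with ties counted ½ (identical to the trapezoidal area
  of the stored points, which the tests assert). The DeLong 95% interval
  comes from pROC. Orientation is explicit: a marker whose *low* values mark
  cases (sphericity) can be reported raw — AUC below 0.5, the orientation in
  which such curves are sometimes published — or flipped
  (`direction = "lower_riskier"`); the pipeline default is raw, with
  `flip_lasp = TRUE` to mirror it.
- **Tertile analysis.** Splits at the empirical 1/3 and 2/3 quantiles
  (linear-interpolation quantiles, R type 7) with boundary ties going to the
  upper tertile, so bin sizes follow the quantile positions (52/52/53 at
  $n = 157$ with distinct values), and tests the resulting 2×3 table by
  chi-square.
- **Score combination.** `combine_with_clinical()` quantifies the added
  discrimination of an imaging score over a clinical risk score by logistic
  regression of the outcome on the clinical score alone and on both, with
  ROC curves of the two fitted-probability vectors. This is the standard
  construction for "adding marker X to score Y" AUC comparisons; other
  choices (category-free reclassification, integrated discrimination
  improvement) are deliberately out of scope.

Clinical scores follow their canonical published component tables
(CHA₂DS₂-VASc: Lip et al. 2010; HAS-BLED: Pisters et al. 2010). Missing
components are a hard error, never a silent zero. One modeling subtlety: in
a prior-stroke case-control design, the CHA₂DS₂-VASc score of interest is
the one that applied *before* the index event, so the stroke-history
component is false for cases' own index stroke; HAS-BLED, in contrast,
describes bleeding risk at assessment time, after the event. `has_bled()`
therefore accepts a `stroke =` override, which the pipeline sets to case
status.

## The synthetic cohort generator

No patient-level data accompany the study design this package targets, so
the generator emulates the two-arm summary structure of its baseline table:
an 83-patient control arm and a 74-patient prior-stroke arm.

Per patient, the three principal-axis diameters $D_i$ are drawn from
independent Gaussians truncated below at 20 mm at the published mean ± SD
per arm (control: 72.4 ± 6.4, 60.11 ± 6.37, 42.72 ± 7.23 mm; stroke:
77.04 ± 10.4, 59.38 ± 10.41, 47.47 ± 11.03 mm). Each diameter is split into
its two radii by a fraction $f_i \sim \mathrm{Beta}(\kappa, \kappa)$
truncated to $(0.15, 0.85)$: $A_i = f_i D_i$, $B_i = (1 - f_i) D_i$. The
construction guarantees $A_i + B_i = D_i$ exactly, so the configured
diameter distributions are reproduced by construction, and the single
concentration parameter $\kappa$ controls within-axis asymmetry and hence
sphericity: mean simulated sphericity is strictly increasing in $\kappa$.

**Calibration.** `calibrate_kappa()` solves for $\kappa$ by bisection of the
simulated mean sphericity against the arm's target (70.54% control, 66.58%
stroke), using 20,000 simulated patients per evaluation under common random
numbers, until the achieved mean is within 0.25 percentage points of the
target. Unreachable targets (e.g. 100%: with unequal axis means, sphericity
cannot reach the spherical limit at any finite $\kappa$) produce an error
reporting the achievable interval. Only the sphericity *mean* is calibrated;
the dispersion is whatever the Beta-split mechanism implies (the published
SDs, 6.95 and 10.34%, are not separately matched) — a documented limitation.
Calibration runs on its own fixed sub-stream (seed 42) so that repeated
cohort draws under different seeds share one calibrated geometry.

Clinical covariates are independent Bernoullis at the published arm
prevalences; age and appendage volume are truncated Gaussians at the
published mean ± SD (age within 18–120 years, appendage volume above 1 cm³);
appendage morphology is categorical over the four standard classes at the
published arm frequencies (normalized, as the printed stroke-arm counts sum
to 71 of 74). Two groups of inputs are not published and were fixed once at
values plausible for an elderly AF population: vascular-disease prevalence
(0.10 control / 0.20 stroke) and the HAS-BLED components other than
hypertension, stroke and age (renal/liver disease, bleeding history, labile
INR, alcohol, antiplatelet/NSAID use; see `control_group_config()` for the
numbers). With these choices the synthetic arms reproduce the published
CHA₂DS₂-VASc means to within a few tenths of a point.

**What the generator does not emulate.** Covariates are sampled
independently because only marginal prevalences are published; real
comorbidities are correlated (hypertension with age, heart failure with
dilation), so synthetic multivariate coefficients should not be read as
estimates of the published ones. Geometry and clinical covariates are
likewise independent given the arm, whereas in patients atrial remodeling
presumably tracks age and disease burden. There is no temporal model of
shape change relative to the event, no measurement error model for the
radii, and the appendage-volume distribution is a truncated Gaussian rather
than a skewed law. Consequently, passing tests on synthetic cohorts
demonstrate that the *machinery* is correct and that the calibrated
two-group geometry difference is detectable at the published sample sizes —
not that the package reproduces patient-level results it has never seen.

**Randomness.** Every stochastic operation takes an explicit seed and draws
from a sub-stream derived by a fixed integer hash of (seed, component-name)
(`derive_seed()`), so any component of a cohort can be regenerated
independently and the whole cohort is a pure function of its seed. RNG state
is saved and restored around every draw, so package calls never disturb the
caller's random stream.

## The pipeline

`run_analysis()` takes a cohort table (the CSV schema of `read_cohort()`)
and produces, in one deterministic pass: the group-comparison table (means ±
SD with the configured two-group test for continuous rows, proportions with
chi-square/Fisher for binary rows, medians [IQR] alongside for the two
clinical scores), univariate odds ratios for the standard variable list, one
multivariate logistic model on that same list (appendage morphology entering
dichotomized as chicken-wing versus non-chicken-wing), the sphericity ROC in
raw orientation, the re-fitted discriminant with LOOCV PIC and the ROC of
its cross-validated posteriors, the sphericity tertile analysis, and the
CHA₂DS₂-VASc ROC alone and with the discriminant added. The multivariate
model includes both the composite clinical score and several of its
components as separate covariates — a deliberately collinear design,
replicated because it is how such models are sometimes published; the
correlation machinery (`pearson_correlation()`) is there to inspect exactly
this.

Reports render to JSON (full precision, byte-identical for identical
inputs), a CSV bundle, or markdown; every number in a rendered report is
recomputable by calling the underlying module function on the stored inputs,
which the test suite spot-checks. A thin command-line front end
(`inst/scripts/lashape-cli.R`) exposes `simulate`, `analyze`, `score` and
`report` subcommands over the same functions.

## Numerical choices and problem sizes

- Logistic fits use IRLS to a deviance tolerance of 1e-14 so that
  closed-form identities (the 2×2 odds ratio and its standard error) hold to
  1e-6 in the tests.
- Discriminant solves go through Cholesky factorization with an explicit
  reciprocal-condition-number guard (1e-12) so near-collinear features fail
  loudly.
- Youden-optimal cutoffs break ties toward higher sensitivity; LOOCV
  threshold optimization breaks ties toward the lower cutoff.
- The confidence level is fixed at 95% with $z = 1.96$ for odds-ratio
  intervals, matching how such tables are conventionally printed.
- Test-suite problem sizes were chosen to keep the full suite fast while
  leaving no asymptotic claim untested: property loops use 1000–1500 random
  measurement sets; LOOCV oracle equivalence uses ten cohorts of up to 60
  subjects; calibration checks use 4000–20,000 simulated patients; the
  qualitative discrimination claims (discriminant beats raw sphericity;
  adding it to the clinical score does not hurt) are asserted over 20
  replicate 157-patient cohorts.

## Known limitations

- The package reproduces published *summary-level* quantities (Welch
  p-values from printed summaries; calibrated sphericity means) exactly or
  to stated tolerance, but patient-level quantities of the original study
  (odds-ratio tables, the specific AUCs and the 0.3185 PIC, the tertile
  percentages) are not recoverable without the original data and are
  deliberately not asserted; on synthetic cohorts the package checks the
  qualitative structure instead.
- One printed p-value in the reference summary structure (the transverse
  diameter row) is not reproducible from its own printed summaries under
  either t-test variant; the package reproduces the four rows that are.
- Sphericity here is the six-radius coefficient-of-variation construction
  only; surface-mesh sphere-fitting definitions from other literature are
  out of scope.
- The discriminant machinery is linear with a single pooled covariance; no
  quadratic or regularized variants are provided.
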