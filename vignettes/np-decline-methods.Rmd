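---
title: "Methods: regression-based change norms and the NP decline metric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regression-based change norms and the NP decline metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npdecline)
```

## The problem

Serial neuropsychological testing should be a sensitive way to catch early
cognitive decline in older adults, but two artifacts of retesting obscure it:
practice effects (scores improve on re-exposure even when ability is stable)
and regression to the mean (extreme baseline scores drift back toward the
population mean). A raw 12-month change score therefore confounds true
decline with both artifacts.

Regression-based change norms absorb them. In a *robustly normal* reference
sample — subjects cognitively normal at baseline who stay normal throughout
follow-up — ordinary least squares predicts the 12-month score from the
baseline score, per test:

$$\hat{y}_{12} = a + b \, y_0 .$$

The intercept absorbs the average practice gain; the slope $b < 1$ encodes
regression to the mean. A tested individual's standardized deviation from
this normative expectation is

$$z = \frac{y_{12} - \hat{y}_{12}}{S_{y.x}},$$

with $S_{y.x} = \sqrt{\mathrm{RSS}/(n-2)}$ the standard error of the
estimate of the norm regression. Averaging $z$ over a six-test battery
(Logical Memory I and II, Trail Making A and B, Animals, Vegetables) gives
the composite **NP decline z-score**; more negative means more decline. A
subject is classified NP+ (decline present) when the composite is at or
below the published ROC-derived cutoff $-0.5808$, which sits at the 28th
percentile of a standard normal reference distribution
(`100 * pnorm(-0.5808)` = `r round(100 * pnorm(-0.5808), 2)`).

The package ships the published six-equation norm set
(`published_norms()`), can refit norms on any reference cohort
(`fit_norm_table()`), scores cohorts (`score_cohort()`), and evaluates NP
decline as a dementia predictor (conversion contrasts, factorial ANCOVA,
Cox models, stratified progression curves).

## Timed scores and the inversion convention

Trail Making completion times are right-skewed, so the timed tests are
analyzed as $-\log_{10}(\text{seconds})$: the log tames the skew and the
sign flip makes higher always mean better, aligning all six tests. The
published timed-test equations are printed as a positive-log regression with
a trailing inversion, $\hat{y} = -(a + b\log_{10} s)$. This is algebraically
identical to regressing on the inverted scale with negated intercept,
$(-a) + b(-\log_{10} s)$; a unit test pins both formulations to machine
precision, and `fit_norm()` stores timed-test fits in the printed
convention. The log base is 10: with the printed Trails-A constants a
30-second baseline predicts a plausible ~30-second follow-up on base-10
inputs, and the printed $S_{y.x}$ of 0.1009 is the right magnitude for
log10-scale residuals, whereas natural-log inputs would imply impossible
times. Whether the original equations were fitted on inverted scores or
inverted afterwards is not documented; under the adopted convention the two
are indistinguishable, so nothing downstream depends on it.

## The synthetic cohorts

Real cohorts of this kind live in access-controlled registries, so the
package generates synthetic ones with the statistical structure the analysis
assumes. Every parameter below is a modeling choice, fixed once; none is an
estimate from registry data.

**Per-test true-score model.** Observed baseline score
$y_0 = A + e_0$, with latent ability $A \sim N(\mu, \sigma_A^2)$ and noise
$e_0 \sim N(0, \sigma_e^2)$; reliability $r = \sigma_A^2 / (\sigma_A^2 +
\sigma_e^2)$ is set to 0.70, a typical serial-testing value. The stable
12-month latent score regresses toward the mean with strength $\rho$
(`retest_slope`) and gains a practice effect $g$:
$y_{12} = \mu + \rho (A - \mu) + g - \delta\, S_{y.x} + e_1$, where
$\delta \ge 0$ is the subject's latent decline in composite-z units (0 for
stable subjects). The implied population regression of $y_{12}$ on $y_0$
has slope $r\rho$, which is how the generator is calibrated: given the
published slope $b$ and $S_{y.x}$, it sets $\rho = b/r$, solves
$\sigma_x^2 (1-r)(\rho^2 r + 1) = S_{y.x}^2$ for the observed baseline
variance, and chooses $g$ to match the published intercept at a plausible
ability mean (13 and 12 story units for Logical Memory I/II, 35 s and 85 s
for Trails A/B, 20 animals, 14 vegetables). The generating truth of each
test therefore *is* the published equation, which is what lets the
norm-recovery and calibration tests use those constants as ground truth.
Scores are clamped to raw-scale bounds (0–25 story units, 1–150 s and
1–300 s, 0–60 for fluency); with the default parameters clamping affects
roughly 1% of draws and is a deliberately retained, realistic
imperfection.

**Decline and diagnosis.** The study generator draws each subject's
12-month diagnostic stratum (NORMAL / impaired-without-MCI / MCI in
proportions 0.691 / 0.069 / 0.240), shifts latent ability by 0, −0.39 and
−1.0 latent SDs respectively, and gives a per-stratum fraction of subjects
(0.24 / 0.26 / 0.32) a latent decline $\delta \sim N(1, 0.4^2)$ truncated
at zero that loads on all six tests simultaneously — a shared factor is
what makes the composite beat any single test. Two mechanisms lower the
expected composite z below zero in the impaired strata: the decliner
mixture, and the ability shift itself (impaired subjects regress toward
their *own* lower mean while the healthy-reference norm predicts regression
toward the reference mean, so stable impaired subjects score below
normative expectation — a real property of healthy-reference change norms).
The per-stratum decline fractions were chosen by closed form so that the
two mechanisms together give NP+ prevalences near 24% / 34% / 55% by
stratum, the group structure the analysis is meant to stratify.

**Dementia and follow-up.** Onset is exponential in continuous time with
log hazard `log(baseline_hazard) + stratum offset + log(2) * delta` —
i.e., the hazard doubles per composite-z unit of true decline — then
snapped to the next scheduled visit, where the diagnosis becomes DEMENTIA
and CDR rises to 1 (mirroring adjudication-at-visit practice). Visits are
annual with ±2 months of uniform jitter; dropout is exponential after the
12-month exam (rate 0.02/month, giving ~59 months mean total follow-up);
administrative censoring applies at 156 months. The baseline hazard
(0.001/person-month) and stratum offsets (0, 0.9, 1.8 on the log scale)
put per-stratum conversion in the mid-single-digit to low-30s percent
range with the NORMAL < impaired < MCI ordering; matching any registry's
exact percentages is a non-goal.

**What the generator does not emulate.** Site heterogeneity, ethnicity
structure, test-version effects, death as a competing risk, learning across
more than two exams (batteries are emitted at baseline and ~12 months
only), and CDR progression independent of the dementia diagnosis (CDR
rises only at conversion, so the CDR sensitivity outcome tracks the
diagnosis outcome among CDR-0 subjects rather than providing a fully
independent criterion). Passing tests therefore demonstrate internal
statistical correctness of the pipeline under a faithful generative model,
not performance on registry data.

## Scoring and evaluation choices

- **Follow-up window:** the exam closest to 12 months within ±6 months
  (annual schedules jitter); configurable in `scoring_policy()`.
- **Missing subtests:** the composite is defined as the mean over all six
  tests, so the default requires all six; `min_subtests` can be relaxed
  (≥ 4 is sensible) for incomplete batteries, with `n_subtests_used`
  always recorded. No imputation.
- **Cutoff boundary:** inclusive (`z <= -0.5808` is NP+), matching the
  "at or below" phrasing of the published percentile; the percentile
  operation uses the same inclusive convention so that classification and
  percentile agree exactly.
- **ROC optimum:** Youden's J over observed-z thresholds, ties broken
  toward the more negative threshold; the derivation criterion behind the
  published cutoff is not restated in the source, and J is the standard
  single-number optimum.
- **Eligibility:** rules are applied in a fixed order (age ≥ 60 →
  non-dementia baseline diagnosis → ≥ 3 exams → > 12 months follow-up →
  no dementia within 12 months) and each exclusion is charged to the first
  failing rule, so the ledger partitions the excluded. "Dementia within 12
  months" is taken as a first dementia diagnosis at ≤ 12 months; a subject
  first demented *at* the ~12-month exam is instead caught by the
  non-demented-at-follow-up scoring rule and dropped there.
- **Survival time origin:** the 12-month exam — NP decline is only
  knowable then, so risk sets are only well-defined from that point
  (`time_origin = "baseline"` is available for comparison).
- **Cox specification:** Efron tie handling (visit-grid snapping produces
  heavy ties; Efron is less biased than Breslow), covariates age, sex and
  education, and the continuous predictor entered as $-z$ so that a hazard
  ratio above 1 means decline is harmful; the per-z coefficient is also
  reported. Both the continuous and the binarized NP± predictor are
  implemented, since the original specification is ambiguous. Records with
  UNKNOWN sex are excluded from covariate-adjusted models with a logged
  count.
- **Chi-squared contrasts:** 2×2 within each stratum, 1 df, no continuity
  correction (large-sample usage; the correction is a flag away).
- **ANCOVA:** the factorial design crosses the 12-month diagnosis with the
  dementia outcome (the alternative crossing with NP status is exposed via
  `second_factor`), with type-III F tests on sum contrasts,
  covariate-adjusted cell means via `emmeans`, and Bonferroni-adjusted
  pairwise contrasts.

## Numerical and testing notes

Cohort files round-trip through CSV with 17-significant-digit decimal text,
so write-then-read is exact. Degenerate norm fits (zero residual variance)
are flagged rather than silently returned; fits require ≥ 3 complete cases
and nonzero baseline variance. Simulation seeds fix every draw;
same-seed cohorts are identical.

The test suite verifies, among other properties: the attenuation identity
(regression slope of follow-up on baseline equals reliability ×
retest slope) against its closed form; norm-parameter recovery on
294-subject reference samples within 3 closed-form OLS standard errors in
≥ 95% of 200 replicates; z calibration (mean within ±0.05, SD within
0.95–1.05) when scoring an independent 10,000-subject stable cohort with
norms fitted on another; recovery of a true hazard ratio of 2 per decline
unit (100 replicates of 5,000 records, mean log-HR within 0.1, ≥ 93%
CI coverage) using a records-level simulator whose hazard is defined on
the *measured* composite — defining truth on the latent decline instead
would make the measured-predictor HR attenuate by the 6-test measurement
error, which is a property of measurement error, not a fault of the Cox
stage; size of the null chi-squared (5% ± 1.5% over 1,000 replicates at
1,000 records each, a size at which the large-sample test is in its
asymptotic regime); and the qualitative prognosis result (NP+ converts
more than NP− in every stratum; progression curves ordered) on the default
6,794-subject simulation. These problem sizes keep the whole suite under a
minute of compute while leaving Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

The norms carry no demographic terms (by design — covariates enter the
survival models instead), so the synthetic ability means are the only
anchor of the raw-score scale. The hazard model is exponential
(constant baseline hazard), which is a simplification; the evaluation
stage makes no such assumption. The CDR sensitivity analysis is
structurally weak in simulation for the reason noted above. And the
published-constant norm set is specific to this six-test battery and
12-month interval; applying it to other intervals or test versions is out
of scope.
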