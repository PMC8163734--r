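---
title: "Methods: instrumental-variable survival analysis of a genetically determined exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instrumental-variable survival analysis of a genetically determined exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mrsurv` implements a Mendelian-randomization pipeline for a continuous
exposure (serum albumin, g/dL) and an interval-detected time-to-event
outcome (incident hypertension) in a longitudinal cohort with biennial
examination visits. This vignette is the package's account of the models,
the synthetic-cohort generator that stands in for access-restricted cohort
data, the numerical choices, and what the calibration studies do and do
not demonstrate.

## The causal problem and the estimators

Ordinary regression of blood-pressure change (or of the hypertension
hazard) on serum albumin is confounded by unmeasured factors `U` (e.g.
subclinical inflammation) that plausibly lower albumin and raise blood
pressure. A genotype `G` that shifts albumin but has no other pathway to
blood pressure is an instrument: random assortment of alleles makes `G`
independent of `U`.

Three estimators operate around this structure:

* **2SLS** (`fit_2sls()`): stage 1 regresses albumin on the coded genotype
  plus covariates; stage 2 regresses the BP-change rate (mmHg/month) on the
  fitted albumin. Standard errors are the classical 2SLS ones — stage-2
  residuals are recomputed at the observed exposure. In the just-identified
  covariate-free case the estimate reduces to the Wald ratio, an identity
  the tests check to 1e-10.
* **Durbin–Wu–Hausman** (`dwh_test()`): implemented in the augmented
  (control-function) form — the stage-1 residual joins the outcome OLS and
  its coefficient is t-tested. The classical contrast form (difference of
  OLS and 2SLS estimates over the difference of their variances, with a
  common residual variance) is kept as a cross-check; the two agree to
  numerical precision on full-rank designs.
* **2SRI / control-function Cox** (`fit_2sri_cox()`): for the
  time-to-event outcome the stage-1 residual is included as an extra
  covariate in a Cox model alongside observed albumin. The exposure
  coefficient is the causal log hazard ratio per g/dL; the residual term's
  p-value doubles as an endogeneity diagnostic. The default CI is the
  naive Wald interval from the stage-2 Cox model (labelled as such); a
  subject-level bootstrap that re-runs both stages
  (`tsri_bootstrap_ci()`) is the recommended alternative since the naive
  interval ignores first-stage uncertainty. Both are exposed and labelled
  because reported CIs in applied work rarely state which was used.

Instrument codings follow the applied convention: IV analyses default to
the dominant coding (carrier vs non-carrier of the minor allele),
configurable to additive or recessive.

## Genetic association scan

SNP QC excludes markers with call rate < 95%, minor allele frequency
< 0.05, or Hardy–Weinberg exact p < 0.001 (boundaries pass). The HWE test
is the exact conditional test: given the allele counts, heterozygote
counts of matching parity are enumerated through a numerically stable
recurrence and the two-sided p-value sums configurations no more probable
than the observed one. An independent log-factorial enumeration oracle
verifies it exhaustively for every table with total at most 50.

The scan fits, per SNP, a maximum-likelihood logistic regression of
hypoalbuminemia status (albumin ≤ 4.0 g/dL) on the genetic term under
additive, dominant and recessive codings, adjusted for age and sex, and
reports the Wald p per coding plus the minimum across the three (min-P)
with the best-model label. The min-P over three correlated codings is
anticonservative relative to any single pre-specified coding; it is a
screening statistic and is deliberately left uncorrected, with the
per-model p-values always emitted alongside. The per-SNP solver is a
damped Newton iteration with the model's p×p Hessian (verified against
`glm` to ~1e-13 and against direct likelihood maximization to 1e-6);
separation and post-missingness monomorphism are flagged as missing
p-values rather than numbers.

Genomic control uses `lambda = median(chi^2) / 0.4549364`. On a null
panel, lambda is computed from the additive-model p-values: the min-P
column is anticonservative by construction and would inflate lambda by
design, not by stratification.

## Survival analysis

`fit_cox()` wraps Newton–Raphson partial-likelihood maximization with
Wald standard errors, 95% CIs `exp(coef ± 1.959964·SE)`, and three named
covariate presets: `model1` (age, sex, smoking), `model2` (model1 plus
baseline SBP/DBP, BMI, waist, hemoglobin, platelet, HbA1c, ALT, gamma-GT,
triglyceride, HDL), `model3` (model2 plus albumin). The default ties
method is Breslow, matching the convention of mainstream survival
software in epidemiology; Efron is available and is preferable when many
events share visit months, which is exactly what a biennial visit grid
produces. The choice is recorded in every output.

The proportional-hazards check is a supremum (Kolmogorov-type) test on
the standardized cumulative score process, with p-values from Gaussian
multiplier resampling including the observed-information correction for
coefficient estimation. Under proportional hazards its size is nominal
(verified by simulation); under strong misspecification the resampled
variance also absorbs some misfit, making the test conservative — it
needs a large score drift to reject, which the power study reflects by
using a large cohort with a mid-follow-up effect reversal.

Covariate-adjusted survival curves use the Breslow baseline cumulative
hazard with the non-stratum covariates fixed at analysis-sample means
(reference-population adjustment).

## Restricted cubic splines

`rcs_basis()` is the restricted truncated-power construction: for knots
`t1 < … < tk`, the basis is `x` plus `k−2` restricted cubic terms scaled
by `(tk − t1)^2`, exactly linear beyond the boundary knots. Default knots
sit at the 5th/35th/65th/95th exposure percentiles (four knots), the
standard compromise between flexibility and stability when nothing is
known about curvature; the choice is configurable and recorded. Curves
are reported relative to a reference albumin of 4.0 g/dL — the
hypoalbuminemia cutoff — so the difference-scale curve is exactly 0 and
the HR-scale curve exactly 1 there, with delta-method pointwise 95% CIs
(width zero at the reference). BP-change curves are in mmHg/month, the
unit of the underlying outcome. The nonlinearity test is a Wald test of
the `k−2` nonlinear coefficients — exact F for linear models, chi-square
for Cox. Pointwise bands are pointwise: their simultaneous coverage over
a whole grid is necessarily below the nominal level, and the tests assess
mean pointwise coverage accordingly.

## The synthetic-cohort generator

No individual-level data from the motivating cohort are available, so the
generator (`sim_config()`, `generate_cohort()`) emulates its structure
with known ground truth:

* **Design**: n = 4325 subjects by default, visits every 24 months up to
  156 months, age ~ Normal(49.5, 8.2), 45.3% male, 25.8% smokers; further
  baseline labs are drawn with plausible marginal moments purely so the
  wider covariate presets can be exercised — they are conveniences, not
  calibration claims.
* **Exposure**: albumin = intercept + per-allele effects of two
  instrument SNPs (MAF 0.30 and 0.25, Binomial(2, MAF) under exact HWE) +
  small age/sex/smoking effects + `c·U` + Gaussian noise, with
  `U ~ Normal(0,1)` unobserved. Defaults give mean albumin ≈ 4.25 g/dL,
  SD ≈ 0.33, and roughly a quarter of subjects at or below 4.0 g/dL.
* **Outcome**: latent hypertension onset is exponential with log-hazard
  `b_alb·albumin + d·U + covariate terms` (constant baseline hazard — the
  minimal shape consistent with a Cox analysis; the default 0.011/month
  targets ~25% cumulative incidence, an assumption since the motivating
  study does not report its event count). Systolic/diastolic BP drift
  linearly with subject slopes tied to `b_bp·albumin + d_bp·U`; emitted
  pre-onset BP is capped just below 140/90 mmHg and post-onset systolic
  BP is floored above it, so the interval-detection rule (first visit
  with BP ≥ 140/90 or medication) fires exactly at the first visit at or
  after latent onset — mirroring how a biennial cohort actually records
  onset. The default causal effects are `b_alb = log(0.654)` per g/dL and
  `b_bp = −0.05` mmHg/month per g/dL, magnitudes in the range reported
  for albumin–BP analyses of comparable cohorts.
* **Confounding**: defaults `c = −0.2`, `d = +0.3` encode a factor that
  lowers albumin and raises the hazard, so naive estimates exaggerate the
  protective association — the direction the closed-form
  omitted-variable-bias oracle (`expected_ols_bias()`) predicts and the
  calibration studies verify.
* **Truth sidecar**: `U`, latent onset times and true effects are written
  to a separate JSON the analysis stages never read.

What the generator does **not** emulate: linkage disequilibrium and
population structure in the null SNP panel (SNPs are independent),
assay-level measurement error models, visit non-attendance, and
time-varying exposures. Passing calibration therefore shows the
estimators recover the effects *under the stated structural assumptions*,
not that those assumptions hold in any real cohort.

## Calibration studies and their problem sizes

`run_calibration_suite()` runs five pre-registered studies (sizes chosen
to characterize the estimators well while keeping the suite comfortably
runnable on one CPU):

1. **IV recovery** — confounded linear configuration, n = 5000, 200
   replicates, with the latent event process switched off
   (`baseline_hazard = 0`) and tight BP noise so the analysis isolates
   the linear-Gaussian pathway the closed-form OLS oracle presumes: mean
   OLS within 15% of `expected_ols_bias()` and more than 3 Monte-Carlo
   SEs from the truth; mean 2SLS within 5% of the truth.
2. **DWH calibration** — the per-allele effect is sized analytically
   (a_g = −0.0404 at MAF 0.30, n = 4325, dominant coding) so the expected
   first-stage F sits near 16, the weak-ish regime of the motivating
   analysis. Size within [0.03, 0.07] at α = 0.05 over 1000 exogenous
   replicates; power ≥ 0.8 over 300 endogenous replicates with strong
   confounding (`c = −0.3`, `d_bp = 0.08`, chosen a priori from the
   noncentrality calculation to put power near 0.95).
3. **2SRI recovery** — true causal HR 0.75 per g/dL, n = 4325, 200
   replicates, both instruments with a strong first stage
   (a_g = −0.25; chosen so the Monte-Carlo SE of the mean log-HR is well
   inside the 10% relative-bias band) and baseline hazard 0.006 keeping
   incidence near 25%. Efron ties are used here to keep the heavy
   visit-grid ties from confounding the estimator-bias question. The
   naive Cox estimate must be biased in the direction of `sign(c·d)`.
4. **GWAS null calibration** — 50,000 independent null SNPs at n = 3000:
   lambda within [0.97, 1.03] (additive p-values) and per-model
   KS-vs-uniform statistics below 0.02.
5. **Nonlinearity-test size** — linear truth, n = 400, 500 replicates:
   rejection rate within [0.02, 0.08].

The same tolerances are asserted by `tests/testthat/test-acceptance.R`;
exact-oracle checks (HWE enumeration, brute-force Cox, hand-computed
KM/log-rank, basis formula, byte-level pipeline reproducibility) run
alongside them.

## Numerical and policy choices

* Hypertension thresholds are inclusive (≥ 140 / ≥ 90 mmHg), matching
  the outcome definition used for the survival models; configurable.
* ΔBP is `last − baseline` over elapsed months (positive = rising BP),
  and the diagnosis visit is excluded from "last" by default (the
  pre-diagnosis reading is the defensible reading of "just before the
  diagnosis"); both controlled by arguments.
* Eligibility exclusions log one reason per subject, first match in the
  order: missing data, prevalent hypertension, diabetes, chronic kidney
  disease, cardiovascular disease, malignancy.
* eGFR is CKD-EPI 2009 without the race coefficient (single-ethnicity
  East-Asian cohort); recorded in output metadata.
* Missing data: complete-case per analysis, never imputation; missing
  dosages are complete-case per SNP.
* Minor-allele orientation is computed per dataset from sample
  frequencies for VCF input (ties keep ALT); TSV dosage input is taken
  at face value so files round-trip byte-identically.
* All randomness flows from one global seed through stage-name hashing
  (`derive_seed()`), so any stage can be re-run in isolation; pipeline
  outputs are byte-identical across runs.
* CIs use the fixed normal quantile 1.959964.

## Known limitations

* A single continuous confounder with linear pathways is the only
  confounding structure generated; pleiotropy (instrument affecting the
  outcome directly) is not simulated, and no pleiotropy-robust
  estimators (MR-Egger, weighted median) are provided.
* 2SRI's consistency in the Cox stage is approximate: the unabsorbed
  part of `U` acts as a frailty and attenuates the exposure coefficient
  slightly (noncollapsibility); the 10% recovery band absorbs this at
  the default confounding strength.
* The supremum PH test is conservative under strong misspecification, as
  noted above.
* The min-P scan's anticonservatism is reported, not corrected.
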