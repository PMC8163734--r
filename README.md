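# mrsurv

Mendelian-randomization analysis of a genetically determined continuous
exposure against an interval-detected time-to-event outcome, built for the
setting of **hypoalbuminemia and incident hypertension** in a biennially
examined longitudinal cohort.

Observational regressions of blood pressure (or hypertension risk) on
serum albumin are confounded by unmeasured factors that move both. If a
genotype `G` shifts albumin but touches blood pressure only through
albumin, it is an instrument, and three estimators recover causal effects:

* **Two-stage least squares (2SLS)** for the linear outcome (BP change,
  mmHg/month per g/dL): regress albumin on `G` + covariates, then the
  outcome on fitted albumin; first-stage F measures instrument strength,
  and the **Durbin–Wu–Hausman test** (stage-1 residual added to the
  outcome OLS) tests exposure endogeneity.
* **Two-stage residual inclusion (2SRI, control function)** for the
  survival outcome: a Cox model on albumin plus the stage-1 residual
  yields the causal log hazard ratio per g/dL, `HR = exp(beta)`, with the
  residual coefficient as an endogeneity diagnostic.

Around the estimators the package provides the full pipeline: a
synthetic-cohort generator with known ground truth (instrument SNPs,
confounder `U` acting on exposure and hazard, visit-grid detection of
hypertension at BP ≥ 140/90 mmHg or antihypertensive use), cohort
derivation (eligibility filters, BP-change rates, CKD-EPI eGFR,
descriptive tables), SNP QC with an exact Hardy–Weinberg test, a
three-genetic-model (additive/dominant/recessive) min-P logistic
association scan with genomic-control lambda and QQ/Manhattan tables, Cox
models with named covariate presets, Kaplan–Meier/log-rank, a supremum
proportional-hazards test, and restricted-cubic-spline dose-response
curves referenced to albumin 4.0 g/dL.

## Worked example

Generate a confounded synthetic cohort (4325 subjects, two instrument
SNPs with a strong first stage, true BP-slope effect −0.05 mmHg/month per
g/dL, true hazard ratio 0.654 per g/dL, confounder lowering albumin and
raising the hazard), then compare naive and instrumented estimates:

```r
library(mrsurv)

cfg <- sim_config(n_subjects = 4325, a_g = -0.25, n_null_snps = 50, seed = 7)
coh <- generate_cohort(cfg, dir = tempfile())
d    <- derive_cohort(read_phenotype_table(coh$paths$phenotype))
elig <- apply_eligibility_filter(d)
p    <- elig$cohort$participants

gt <- align_genotypes(elig$cohort, read_genotypes(coh$paths$genotypes))
z  <- encode_genetic_model(gt$dosage[, "instr_1"], "dominant")
ok <- !is.na(p$delta_sbp) & !is.na(z)

fit_ols(p$delta_sbp[ok], p$albumin[ok], p[ok, c("age", "male")])
#> OLS estimate (adjusted for: age+male)
#>   beta = -0.0737  SE = 0.0035  P = 2.287e-93  (n = 3444)

fit_2sls(p$delta_sbp[ok], p$albumin[ok], z[ok], p[ok, c("age", "male")])
#> TSLS estimate (adjusted for: age+male)
#>   beta = -0.0507  SE = 0.0094  P = 6.161e-08  (n = 3444)
#>   first-stage F = 562.96

dwh_test(p$delta_sbp[ok], p$albumin[ok], z[ok], p[ok, c("age", "male")])$p
#> [1] 0.007743

ok2 <- !is.na(z)
fit_2sri_cox(p$time_month[ok2], p$event[ok2], p$albumin[ok2], z[ok2],
             p[ok2, c("age", "male", "smoker")])
#> Two-stage residual inclusion (control function) Cox estimator
#>   causal HR per exposure unit = 0.572  (95% CI 0.375-0.871, wald)
#>   residual term p = 0.09795 (endogeneity diagnostic)
#>   first-stage F = 597.88; n = 3631, events = 1011; ties = breslow
```

Reading the numbers: naive OLS (−0.074) overstates the protective albumin
effect because the simulated confounder lowers albumin while raising BP;
2SLS recovers the true −0.05 within its standard error, and the DWH test
detects the endogeneity (p = 0.008). On the survival side the naive Cox
HR for albumin in this draw is 0.417 — far more protective than the true
0.654 — while the control-function estimate (0.572, CI 0.375–0.871) pulls
back toward the truth.

The whole analysis also runs as one call writing plot-ready TSVs plus a
JSON manifest:

```r
m <- run_pipeline(run_config(simulation = cfg, out_dir = "out", seed = 7))
```

or from a shell via the thin wrapper
`Rscript inst/cli/mrsurv.R pipeline --seed 7 --out out`.

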