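Package: mrsurv
Title: Mendelian Randomization for Time-to-Event Outcomes in Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end instrumental-variable (Mendelian randomization)
    analysis pipeline for genetically determined exposures and incident
    disease in longitudinal cohort studies, motivated by the analysis of
    genetically determined hypoalbuminemia as a risk factor for incident
    hypertension. Provides a synthetic-cohort generator with known ground
    truth (instrument SNPs, a confounded continuous exposure, and
    interval-detected time-to-event outcomes on a biennial visit grid),
    cohort derivation (eligibility filters, incident-hypertension detection,
    blood-pressure change rates, CKD-EPI eGFR, descriptive tables), SNP
    quality control with an exact Hardy-Weinberg test and a three-genetic-
    model (additive/dominant/recessive) min-P logistic association scan with
    genomic-control diagnostics, ordinary and two-stage least-squares
    estimation with first-stage F and Durbin-Wu-Hausman endogeneity testing,
    Cox proportional-hazards models with Kaplan-Meier/log-rank and
    supremum-type proportional-hazards checks, two-stage residual-inclusion
    (control-function) causal hazard-ratio estimation, and restricted cubic
    spline dose-response curves against a reference exposure value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
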