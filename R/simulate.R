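# Synthetic-cohort generator: instrument SNPs -> confounded continuous
# exposure (serum albumin, g/dL) -> interval-detected time-to-hypertension
# on a biennial visit grid, with ground truth retained for recovery tests.

#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the data-generating process: instrument SNPs,
#' the first-stage genetic effect on serum albumin, an unobserved standard
#' normal confounder `U` acting on both the exposure and the outcome, the
#' causal effects of albumin on the hypertension log-hazard and on the
#' monthly blood-pressure slope, and the visit-grid design of a biennial
#' longitudinal survey.
#'
#' Defaults emulate a mid-aged Korean community cohort: n = 4325 subjects,
#' follow-up 156 months with visits every 24 months, mean serum albumin
#' about 4.25 g/dL (roughly a quarter of subjects at or below the 4.0 g/dL
#' hypoalbuminemia cutoff), and a baseline hazard targeting roughly 25%
#' cumulative incidence of hypertension.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param maf_instrument Minor allele frequencies of the instrument SNPs,
#'   each in (0, 0.5]. Length gives the number of instruments (default 2).
#' @param a_g Per-minor-allele effect on albumin, g/dL (recycled across
#'   instruments).
#' @param c_alb Effect of the unobserved confounder `U` on albumin, g/dL per
#'   unit `U`.
#' @param d_hz Effect of `U` on the hypertension log-hazard.
#' @param d_bp Effect of `U` on the monthly systolic BP slope, mmHg/month
#'   per unit `U`.
#' @param b_alb True causal effect of albumin on the log-hazard, per g/dL.
#' @param b_bp True causal effect of albumin on the SBP slope, mmHg/month
#'   per g/dL.
#' @param b_bp_dbp Same for the DBP slope (default 0).
#' @param alb_sd Residual SD of albumin, g/dL (> 0 except in degenerate
#'   test limits).
#' @param alb_intercept Albumin intercept, g/dL.
#' @param alb_age,alb_female,alb_smoker Covariate effects on albumin
#'   (per year of age centred at 49.5; female vs male; smoker vs not).
#' @param hz_age,hz_male Covariate effects on the log-hazard (per year of
#'   age centred at 49.5; male vs female).
#' @param baseline_hazard Baseline hazard, events per month (>= 0).
#' @param visit_interval Months between visits (default 24, a biennial
#'   survey).
#' @param max_followup Maximum follow-up, months.
#' @param n_null_snps Number of phenotype-independent null-panel SNPs.
#' @param bp_noise_sd Visit-level BP measurement noise SD, mmHg (three-
#'   reading averages; default 4).
#' @param slope_sd SD of the subject-specific BP slope residual,
#'   mmHg/month.
#' @param sbp_slope_intercept,dbp_slope_intercept Intercepts of the BP
#'   slope models, mmHg/month.
#' @param sbp_baseline_mean,sbp_baseline_sd,dbp_baseline_mean,dbp_baseline_sd
#'   Baseline BP distribution, mmHg.
#' @param med_prob Probability that a subject starts antihypertensive
#'   medication from the first post-onset visit.
#' @param missing_rate Fraction of subjects with missing baseline albumin
#'   (exercises the missing-data exclusion path).
#' @param geno_missing_rate Per-genotype missingness rate.
#' @param excl_rates Named prevalences of baseline exclusion conditions
#'   (`htn`, `dm`, `ckd`, `cvd`, `cancer`).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 200, seed = 7)
#' cfg$visit_interval
sim_config <- function(n_subjects = 4325,
                       maf_instrument = c(0.30, 0.25),
                       a_g = -0.05,
                       c_alb = -0.2,
                       d_hz = 0.3,
                       d_bp = 0.02,
                       b_alb = log(0.654),
                       b_bp = -0.05,
                       b_bp_dbp = 0,
                       alb_sd = 0.25,
                       alb_intercept = 4.32,
                       alb_age = -0.007,
                       alb_female = 0.02,
                       alb_smoker = -0.07,
                       hz_age = 0.02,
                       hz_male = 0.15,
                       baseline_hazard = 0.011,
                       visit_interval = 24,
                       max_followup = 156,
                       n_null_snps = 200,
                       bp_noise_sd = 4,
                       slope_sd = 0.03,
                       sbp_slope_intercept = 0.26,
                       dbp_slope_intercept = 0.02,
                       sbp_baseline_mean = 113,
                       sbp_baseline_sd = 10,
                       dbp_baseline_mean = 76,
                       dbp_baseline_sd = 7,
                       med_prob = 0.4,
                       missing_rate = 0.02,
                       geno_missing_rate = 0.005,
                       excl_rates = c(htn = 0.06, dm = 0.05, ckd = 0.01,
                                      cvd = 0.02, cancer = 0.01),
                       seed = 1L) {
  cfg <- as.list(environment())
  check_number(n_subjects, "n_subjects", lower = 2)
  if (!is.numeric(maf_instrument) || length(maf_instrument) < 1 ||
      any(maf_instrument <= 0) || any(maf_instrument > 0.5)) {
    stop_mrsurv("'maf_instrument' must be frequencies in (0, 0.5]",
                class = "mrsurv_parameter_error")
  }
  check_number(alb_sd, "alb_sd", lower = 0)
  check_number(bp_noise_sd, "bp_noise_sd", lower = 0)
  check_number(slope_sd, "slope_sd", lower = 0)
  check_number(baseline_hazard, "baseline_hazard", lower = 0)
  if (visit_interval <= 0) {
    stop_mrsurv("'visit_interval' must be > 0", class = "mrsurv_parameter_error")
  }
  check_number(max_followup, "max_followup", lower = visit_interval)
  check_number(n_null_snps, "n_null_snps", lower = 0)
  check_number(missing_rate, "missing_rate", lower = 0, upper = 0.99)
  check_number(geno_missing_rate, "geno_missing_rate", lower = 0, upper = 0.5)
  check_number(seed, "seed")
  for (nm in c("a_g", "c_alb", "d_hz", "d_bp", "b_alb", "b_bp", "b_bp_dbp")) {
    check_number(cfg[[nm]], nm)
  }
  cfg$n_subjects <- as.integer(n_subjects)
  cfg$n_null_snps <- as.integer(n_null_snps)
  cfg$a_g <- rep_len(a_g, length(maf_instrument))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d, instruments: %d (MAF %s), null SNPs: %d\n",
              x$n_subjects, length(x$maf_instrument),
              paste(format(x$maf_instrument), collapse = ", "), x$n_null_snps))
  cat(sprintf("  first stage a_g = %s g/dL per allele; confounder c = %s, d = %s\n",
              paste(format(x$a_g), collapse = ", "),
              format(x$c_alb), format(x$d_hz)))
  cat(sprintf("  causal effects: log-HR %s per g/dL; SBP slope %s mmHg/month per g/dL\n",
              format(x$b_alb), format(x$b_bp)))
  cat(sprintf("  visits every %s months up to %s months; baseline hazard %s/month\n",
              format(x$visit_interval), format(x$max_followup),
              format(x$baseline_hazard)))
  invisible(x)
}

# Baseline covariates echoing the margins of a mid-aged Korean community
# cohort; conveniences for realism, not calibration claims.
simulate_covariates <- function(config) {
  set.seed(derive_seed(config$seed, "covariates"))
  n <- config$n_subjects
  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = round(pmin(pmax(stats::rnorm(n, 49.5, 8.2), 40), 70), 1),
    sex = ifelse(stats::runif(n) < 0.453, "M", "F"),
    smoker = as.integer(stats::runif(n) < 0.258),
    bmi = round(pmax(stats::rnorm(n, 24.0, 3.1), 15), 1),
    waist = round(pmax(stats::rnorm(n, 80.3, 8.5), 55), 1),
    hemoglobin = round(pmax(stats::rnorm(n, 13.4, 1.5), 8), 1),
    platelet = round(pmax(stats::rnorm(n, 262, 61), 80)),
    hba1c = round(pmax(stats::rnorm(n, 5.5, 0.34), 4.2), 2),
    alt = round(pmax(stats::rnorm(n, 25.7, 15), 5), 1),
    ggt = round(pmax(stats::rnorm(n, 27.7, 20), 5), 1),
    tg = round(pmax(stats::rnorm(n, 138.6, 87), 30), 1),
    hdl = round(pmax(stats::rnorm(n, 45.2, 10), 20), 1),
    creatinine = round(pmax(stats::rnorm(n, 0.85, 0.15), 0.4), 2),
    flag_htn = as.integer(stats::runif(n) < config$excl_rates[["htn"]]),
    flag_dm = as.integer(stats::runif(n) < config$excl_rates[["dm"]]),
    flag_ckd = as.integer(stats::runif(n) < config$excl_rates[["ckd"]]),
    flag_cvd = as.integer(stats::runif(n) < config$excl_rates[["cvd"]]),
    flag_cancer = as.integer(stats::runif(n) < config$excl_rates[["cancer"]]),
    stringsAsFactors = FALSE
  )
}

#' Simulate genotypes for the instrument SNPs and a null panel
#'
#' Instrument SNP dosages are drawn as Binomial(2, MAF) — i.e. under exact
#' Hardy-Weinberg equilibrium — and null-panel SNPs are drawn independently
#' of every phenotype, with MAFs uniform on (0.05, 0.5) so they pass the
#' default QC bounds.
#'
#' @param config A [sim_config()] object.
#' @return A [genotype_matrix] with instruments first, then null SNPs.
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_subjects = 50, n_null_snps = 5))
#' dim(g$dosage)
simulate_genotypes <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- config$n_subjects
  k_i <- length(config$maf_instrument)
  k_0 <- config$n_null_snps
  maf_null <- if (k_0 > 0) stats::runif(k_0, 0.05, 0.5) else numeric(0)
  mafs <- c(config$maf_instrument, maf_null)
  dos <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), integer(n))
  if (n == 1) dos <- matrix(dos, nrow = 1)
  if (config$geno_missing_rate > 0) {
    miss <- stats::runif(length(dos)) < config$geno_missing_rate
    dos[miss] <- NA_integer_
  }
  ids <- c(sprintf("instr_%d", seq_len(k_i)),
           if (k_0 > 0) sprintf("null_%05d", seq_len(k_0)))
  colnames(dos) <- ids
  rownames(dos) <- sprintf("S%05d", seq_len(n))
  info <- data.frame(
    snp_id = ids,
    chrom = c(c(6L, 9L, sample(1:22, max(0, k_i - 2), replace = TRUE))[seq_len(k_i)],
              if (k_0 > 0) sample(1:22, k_0, replace = TRUE)),
    pos = sample.int(2e8, k_i + k_0),
    ref = "A", alt = "G",
    type = c(rep("instrument", k_i), rep("null", k_0)),
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, info)
}

#' Simulate the exposure (serum albumin) with genetic and confounded parts
#'
#' Albumin is an intercept plus per-allele instrument effects, covariate
#' effects (age, sex, smoking), a confounder term `c_alb * U` with
#' `U ~ Normal(0, 1)`, and Gaussian noise. `U` is returned so it can be
#' stored in the truth sidecar; the emitted cohort files never contain it.
#'
#' @param genotypes A [genotype_matrix]; instrument columns are those whose
#'   `info$type == "instrument"`.
#' @param covariates Data frame with `age`, `sex`, `smoker` rows aligned to
#'   the genotype rows.
#' @param config A [sim_config()].
#' @param u Optional confounder vector (drawn internally if `NULL`).
#' @return A list with `albumin` (g/dL) and `u`.
#' @export
simulate_exposure <- function(genotypes, covariates, config, u = NULL) {
  dos <- genotypes$dosage
  if (nrow(dos) != nrow(covariates)) {
    stop_mrsurv("genotype rows (%d) and covariate rows (%d) differ",
                nrow(dos), nrow(covariates), class = "mrsurv_shape_error")
  }
  set.seed(derive_seed(config$seed, "exposure"))
  instr <- which(genotypes$info$type == "instrument")
  n <- nrow(dos)
  if (is.null(u)) u <- stats::rnorm(n)
  g_term <- if (length(instr) > 0) {
    gd <- dos[, instr, drop = FALSE]
    gd[is.na(gd)] <- 0  # truth-side convenience; emitted dosages keep NA
    as.numeric(gd %*% config$a_g)
  } else 0
  alb <- config$alb_intercept + g_term +
    config$alb_age * (covariates$age - 49.5) +
    config$alb_female * (covariates$sex == "F") +
    config$alb_smoker * covariates$smoker +
    config$c_alb * u +
    stats::rnorm(n, 0, config$alb_sd)
  list(albumin = alb, u = u)
}

#' Simulate follow-up visits and the latent hypertension onset process
#'
#' Latent onset times are exponential with subject hazard
#' `baseline_hazard * exp(b_alb * albumin + d_hz * U + covariate terms)`.
#' Visit-level BP drifts linearly with a subject slope tied to
#' `b_bp * albumin`; before onset the emitted BP is capped just below the
#' 140/90 mmHg diagnostic threshold, and from the first post-onset visit
#' systolic BP is floored at 141 mmHg (and medication may start), so the
#' downstream detection rule fires exactly at the first visit on or after
#' onset. Censoring occurs at the last grid visit.
#'
#' @param exposure Albumin vector, g/dL (finite).
#' @param covariates Covariate data frame (needs `age`, `sex`).
#' @param u Confounder vector as returned by [simulate_exposure()].
#' @param config A [sim_config()].
#' @return List with `visits` (long data frame: subject_id, visit_month,
#'   sbp, dbp, med_flag) and `latent` (onset month, detection month or NA,
#'   event indicator, true SBP/DBP slopes).
#' @export
simulate_followup <- function(exposure, covariates, u, config) {
  if (any(!is.finite(exposure))) {
    stop_mrsurv("exposure must be finite", class = "mrsurv_parameter_error")
  }
  set.seed(derive_seed(config$seed, "followup"))
  n <- length(exposure)
  lin <- config$b_alb * exposure + config$d_hz * u +
    config$hz_age * (covariates$age - 49.5) +
    config$hz_male * (covariates$sex == "M")
  haz <- config$baseline_hazard * exp(lin)
  if (any(!is.finite(haz))) {
    stop_mrsurv("non-finite hazard; check b_alb/d_hz/baseline_hazard",
                class = "mrsurv_parameter_error")
  }
  onset <- ifelse(haz > 0, stats::rexp(n) / haz, Inf)

  months <- seq(0, config$max_followup, by = config$visit_interval)
  k <- length(months)
  slope_s <- config$sbp_slope_intercept + config$b_bp * exposure +
    config$d_bp * u + stats::rnorm(n, 0, config$slope_sd)
  slope_d <- config$dbp_slope_intercept + config$b_bp_dbp * exposure +
    stats::rnorm(n, 0, config$slope_sd)
  base_s <- stats::rnorm(n, config$sbp_baseline_mean, config$sbp_baseline_sd)
  base_d <- stats::rnorm(n, config$dbp_baseline_mean, config$dbp_baseline_sd)
  med_user <- stats::runif(n) < config$med_prob

  tmat <- matrix(months, n, k, byrow = TRUE)
  sbp <- base_s + slope_s * tmat +
    matrix(stats::rnorm(n * k, 0, config$bp_noise_sd), n, k)
  dbp <- base_d + slope_d * tmat +
    matrix(stats::rnorm(n * k, 0, config$bp_noise_sd), n, k)
  post <- tmat >= onset & tmat > 0
  sbp[!post] <- pmin(sbp[!post], 139)
  dbp[!post] <- pmin(dbp[!post], 89)
  sbp[post] <- pmax(sbp[post], 141)
  med <- post & med_user

  detect <- apply(post, 1, function(r) if (any(r)) months[which(r)[1]] else NA_real_)
  visits <- data.frame(
    subject_id = rep(covariates$subject_id, each = k),
    visit_month = rep(months, n),
    sbp = round(as.vector(t(sbp)), 1),
    dbp = round(as.vector(t(dbp)), 1),
    med_flag = as.integer(as.vector(t(med))),
    stringsAsFactors = FALSE
  )
  latent <- data.frame(
    subject_id = covariates$subject_id,
    onset_month = onset,
    detect_month = detect,
    event = as.integer(!is.na(detect)),
    slope_sbp = slope_s,
    slope_dbp = slope_d,
    stringsAsFactors = FALSE
  )
  list(visits = visits, latent = latent)
}

#' Generate a full synthetic cohort (phenotype + genotype files + truth)
#'
#' Composes [simulate_genotypes()], [simulate_exposure()] and
#' [simulate_followup()], injects baseline albumin missingness and baseline
#' exclusion flags, and (optionally) writes the two standard input files
#' consumed by the readers plus a JSON truth sidecar. The truth object is
#' returned separately so pipeline stages cannot read it.
#'
#' @param config A [sim_config()].
#' @param dir Output directory; if `NULL`, nothing is written.
#' @return List with `phenotype` (long visit table with baseline covariates
#'   repeated per row), `genotypes` (a [genotype_matrix]), `truth`, and
#'   `paths` (when written).
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n_subjects = 100, n_null_snps = 10))
#' head(coh$phenotype)
generate_cohort <- function(config = sim_config(), dir = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cov <- simulate_covariates(config)
  gen <- simulate_genotypes(config)
  exp_ <- simulate_exposure(gen, cov, config)
  fup <- simulate_followup(exp_$albumin, cov, exp_$u, config)

  set.seed(derive_seed(config$seed, "missingness"))
  alb_out <- round(exp_$albumin, 2)
  alb_out[stats::runif(config$n_subjects) < config$missing_rate] <- NA_real_
  cov$albumin <- alb_out

  ph <- merge(fup$visits, cov, by = "subject_id", sort = FALSE)
  ph <- ph[order(ph$subject_id, ph$visit_month), ]
  rownames(ph) <- NULL
  first <- c("subject_id", "visit_month", "sbp", "dbp", "med_flag", "albumin",
             "age", "sex", "smoker")
  ph <- ph[, c(first, setdiff(names(ph), first))]

  truth <- list(
    b_alb = config$b_alb, b_bp = config$b_bp, b_bp_dbp = config$b_bp_dbp,
    c_alb = config$c_alb, d_hz = config$d_hz, d_bp = config$d_bp,
    a_g = config$a_g, seed = config$seed,
    u = exp_$u, albumin_true = exp_$albumin,
    onset_month = fup$latent$onset_month,
    detect_month = fup$latent$detect_month,
    event = fup$latent$event,
    slope_sbp = fup$latent$slope_sbp,
    slope_dbp = fup$latent$slope_dbp
  )
  out <- list(phenotype = ph, genotypes = gen, truth = truth, paths = NULL)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p_ph <- file.path(dir, "phenotype.tsv")
    p_gt <- file.path(dir, "genotypes.tsv")
    p_tr <- file.path(dir, "truth.json")
    write_tsv(ph, p_ph)
    write_genotypes_tsv(gen, p_gt)
    tr <- truth
    tr$onset_month[!is.finite(tr$onset_month)] <- -1  # JSON has no Inf
    write_json_file(tr, p_tr)
    out$paths <- list(phenotype = p_ph, genotypes = p_gt, truth = p_tr)
  }
  out
}

#' Closed-form probability limit of naive OLS under confounding
#'
#' For the linear-Gaussian blood-pressure-change outcome, ordinary least
#' squares of the BP slope on albumin (adjusting for the generated
#' covariates) converges to the omitted-variable-bias expression
#' `b_bp + d_bp * c_alb * Var(U) / Var(albumin)`, where `Var(albumin)` is
#' the exposure variance net of the adjusted covariates (genetic +
#' confounder + noise components) and `Var(U) = 1`. Used as the oracle for
#' what naive OLS converges to in the calibration studies.
#'
#' @param config A [sim_config()].
#' @param var_albumin Optional override of the exposure variance.
#' @return Probability limit of the OLS slope, mmHg/month per g/dL.
#' @export
#' @examples
#' expected_ols_bias(sim_config(c_alb = 0))  # equals b_bp
expected_ols_bias <- function(config, var_albumin = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (is.null(var_albumin)) {
    var_g <- sum(config$a_g^2 * 2 * config$maf_instrument * (1 - config$maf_instrument))
    var_albumin <- var_g + config$c_alb^2 + config$alb_sd^2
  }
  if (var_albumin <= 0) {
    stop_mrsurv("exposure variance is zero; OLS limit undefined",
                class = "mrsurv_undefined_error")
  }
  config$b_bp + config$d_bp * config$c_alb * 1 / var_albumin
}
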