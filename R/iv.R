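# Instrumental-variable estimators: OLS baseline, two-stage least squares
# with first-stage F, the Durbin-Wu-Hausman endogeneity test (augmented
# control-function regression, with the classical contrast form as a
# cross-check), and the two-stage residual-inclusion Cox estimator.

# covariate data frame -> numeric design matrix (no intercept column)
design_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.matrix(covariates)) {
    storage.mode(covariates) <- "double"
    return(covariates)
  }
  m <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  m[, -1, drop = FALSE]
}

# least squares with rank diagnostics; classical (homoskedastic) SEs
ols_core <- function(y, X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_mrsurv("collinear design; offending column(s): %s",
                paste(bad, collapse = ", "), class = "mrsurv_rank_error")
  }
  beta <- qr.coef(qr_x, y)
  fitted <- qr.fitted(qr_x, y)
  resid <- y - fitted
  df <- length(y) - ncol(X)
  if (df < 1) {
    stop_mrsurv("n (%d) must exceed number of parameters (%d)",
                length(y), ncol(X), class = "mrsurv_parameter_error")
  }
  sigma2 <- sum(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  # undo pivoting
  xtx_inv <- xtx_inv[order(qr_x$pivot), order(qr_x$pivot), drop = FALSE]
  se <- stats::setNames(sqrt(sigma2 * diag(xtx_inv)), colnames(X))
  list(beta = beta, se = se, sigma2 = sigma2, resid = resid, fitted = fitted,
       df = df, xtx_inv = xtx_inv)
}

new_iv_fit <- function(estimator, beta, se, p, n, df, first_stage_F = NA_real_,
                       dwh_p = NA_real_, coef_table = NULL, covariate_label = "none") {
  structure(list(estimator = estimator, beta = beta, se = se, p = p, n = n,
                 df = df, first_stage_F = first_stage_F, dwh_p = dwh_p,
                 coefficients = coef_table, covariate_label = covariate_label),
            class = "iv_fit")
}

#' Ordinary least squares estimate of an exposure effect
#'
#' Classical linear regression of the outcome on the exposure plus
#' covariates, with homoskedastic standard errors and a two-sided t-test.
#'
#' @param outcome Numeric outcome vector (e.g. BP change, mmHg/month).
#' @param exposure Numeric exposure vector (e.g. albumin, g/dL).
#' @param covariates Optional covariate data frame / matrix.
#' @return An `iv_fit` object (estimator `"ols"`).
#' @export
#' @examples
#' fit <- fit_ols(rnorm(50), rnorm(50))
#' coef(fit)
fit_ols <- function(outcome, exposure, covariates = NULL) {
  stopifnot(length(outcome) == length(exposure))
  if (any(!is.finite(outcome)) || any(!is.finite(exposure))) {
    stop_mrsurv("outcome and exposure must be finite",
                class = "mrsurv_parameter_error")
  }
  C <- design_matrix(covariates, length(outcome))
  X <- cbind(`(Intercept)` = 1, exposure = exposure, C)
  f <- ols_core(outcome, X)
  tval <- f$beta / f$se
  p <- 2 * stats::pt(-abs(tval), f$df)
  ct <- data.frame(term = colnames(X), beta = unname(f$beta), se = unname(f$se),
                   p = unname(p), stringsAsFactors = FALSE)
  fit <- new_iv_fit("ols", unname(f$beta["exposure"]), unname(f$se["exposure"]),
                    unname(p["exposure"]), length(outcome), f$df,
                    coef_table = ct,
                    covariate_label = if (is.null(C)) "none" else paste(colnames(C), collapse = "+"))
  fit$rss <- sum(f$resid^2)
  fit$residuals <- f$resid
  fit
}

#' Two-stage least squares with a genetic instrument
#'
#' Stage 1 regresses the exposure on the instrument(s) plus covariates;
#' stage 2 regresses the outcome on the fitted exposure plus the same
#' covariates. Standard errors are the classical 2SLS ones: stage-2
#' residuals are recomputed at the observed (not fitted) exposure. The
#' first-stage F is the Wald F for the instrument term(s). F below 10
#' triggers a weak-instrument warning; a constant instrument is an error.
#'
#' @param outcome,exposure Numeric vectors.
#' @param instrument Coded genotype vector or matrix (e.g. dominant-coded
#'   dosage).
#' @param covariates Optional covariates, identical across both stages.
#' @return An `iv_fit` (estimator `"tsls"`) with `first_stage_F`.
#' @export
fit_2sls <- function(outcome, exposure, instrument, covariates = NULL) {
  z <- as.matrix(instrument)
  if (is.null(colnames(z))) colnames(z) <- paste0("instrument", seq_len(ncol(z)))
  stopifnot(length(outcome) == length(exposure), nrow(z) == length(outcome))
  if (any(apply(z, 2, stats::sd) == 0)) {
    stop_mrsurv("instrument does not vary (weak-instrument degenerate case)",
                class = "mrsurv_weak_instrument_error")
  }
  C <- design_matrix(covariates, length(outcome))
  X1 <- cbind(`(Intercept)` = 1, z, C)
  s1 <- ols_core(exposure, X1)
  iz <- seq_len(ncol(z)) + 1L
  # Wald F for the instrument block
  Vz <- s1$sigma2 * s1$xtx_inv[iz, iz, drop = FALSE]
  bz <- s1$beta[iz]
  Fstat <- as.numeric(t(bz) %*% solve(Vz, bz)) / length(iz)
  if (Fstat < 10) {
    warning(sprintf("weak instrument: first-stage F = %.2f < 10", Fstat))
  }
  xhat <- s1$fitted
  X2 <- cbind(`(Intercept)` = 1, exposure = xhat, C)
  s2 <- ols_core(outcome, X2)
  # classical 2SLS covariance: residuals at observed exposure
  X2obs <- cbind(`(Intercept)` = 1, exposure = exposure, C)
  e <- outcome - as.numeric(X2obs %*% s2$beta)
  sigma2 <- sum(e^2) / s2$df
  se <- sqrt(sigma2 * diag(s2$xtx_inv))
  names(se) <- colnames(X2)
  tval <- s2$beta / se
  p <- 2 * stats::pt(-abs(tval), s2$df)
  ct <- data.frame(term = colnames(X2), beta = unname(s2$beta), se = unname(se),
                   p = unname(p), stringsAsFactors = FALSE)
  fit <- new_iv_fit("tsls", unname(s2$beta["exposure"]), unname(se["exposure"]),
                    unname(p["exposure"]), length(outcome), s2$df,
                    first_stage_F = Fstat, coef_table = ct,
                    covariate_label = if (is.null(C)) "none" else paste(colnames(C), collapse = "+"))
  fit$stage1_residuals <- s1$resid
  fit
}

#' Durbin-Wu-Hausman endogeneity test
#'
#' Default form: augmented (control-function) regression — the stage-1
#' residual is added to the outcome OLS and its coefficient tested with a
#' two-sided t-test. The classical contrast form (difference between the
#' OLS and 2SLS estimates weighted by the difference of their variances,
#' with a common residual-variance estimate) is available as a
#' cross-check and is numerically equivalent on full-rank designs.
#'
#' @param outcome,exposure,instrument,covariates As in [fit_2sls()].
#' @param form `"augmented"` or `"contrast"`.
#' @return List with `statistic` (t for augmented; equal to the signed
#'   square root of the contrast chi-square), `df`, `p`, `applicable`.
#' @export
dwh_test <- function(outcome, exposure, instrument, covariates = NULL,
                     form = c("augmented", "contrast")) {
  form <- match.arg(form)
  z <- as.matrix(instrument)
  C <- design_matrix(covariates, length(outcome))
  X1 <- cbind(1, z, C)
  s1 <- ols_core(exposure, X1)
  v <- s1$resid
  if (stats::sd(v) < 1e-12 * max(1, stats::sd(exposure))) {
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                applicable = FALSE,
                note = "exposure fully determined by instrument; stage-1 residuals are zero"))
  }
  Xa <- cbind(`(Intercept)` = 1, exposure = exposure, C, v = v)
  sa <- ols_core(outcome, Xa)
  ta <- sa$beta["v"] / sa$se["v"]
  pa <- 2 * stats::pt(-abs(ta), sa$df)
  if (form == "augmented") {
    return(list(statistic = unname(ta), df = sa$df, p = unname(pa),
                applicable = TRUE))
  }
  b_iv <- fit_2sls(outcome, exposure, instrument, covariates)
  b_ols <- fit_ols(outcome, exposure, covariates)
  # variances recomputed with the common sigma^2 from the augmented fit
  X2h <- cbind(1, exposure - v, C)   # fitted exposure = observed - residual
  Xo <- cbind(1, exposure, C)
  a_iv <- chol2inv(qr.R(qr(X2h)))[2, 2]
  a_ols <- chol2inv(qr.R(qr(Xo)))[2, 2]
  stat <- (b_iv$beta - b_ols$beta)^2 / (sa$sigma2 * (a_iv - a_ols))
  list(statistic = sign(b_iv$beta - b_ols$beta) * sqrt(stat), df = sa$df,
       p = 2 * stats::pt(-sqrt(stat), sa$df), applicable = TRUE)
}

#' Two-stage residual inclusion (control function) Cox estimator
#'
#' Stage 1: OLS of the exposure on the instrument plus covariates, keeping
#' residuals. Stage 2: Cox proportional-hazards model on the exposure, the
#' stage-1 residual, and the covariates. The exposure coefficient is the
#' causal log hazard ratio per exposure unit; the residual coefficient's
#' p-value is reported as an endogeneity diagnostic. The default 95% CI is
#' the naive Wald interval from the stage-2 Cox model;
#' [tsri_bootstrap_ci()] provides the recommended subject-level bootstrap
#' alternative that propagates first-stage uncertainty.
#'
#' @param time Follow-up time, months (> 0).
#' @param event Event indicator (0/1 or logical).
#' @param exposure Numeric exposure.
#' @param instrument Coded genotype vector/matrix.
#' @param covariates Optional covariates.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `tsri_fit` object.
#' @export
fit_2sri_cox <- function(time, event, exposure, instrument, covariates = NULL,
                         ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  z <- as.matrix(instrument)
  if (all(apply(z, 2, stats::sd) == 0)) {
    stop_mrsurv("instrument does not vary", class = "mrsurv_weak_instrument_error")
  }
  C <- design_matrix(covariates, length(exposure))
  X1 <- cbind(1, z, C)
  s1 <- ols_core(exposure, X1)
  v <- s1$resid
  if (stats::sd(v) < 1e-12) {
    stop_mrsurv("stage-1 residuals are collinear with the exposure (zero variance)",
                class = "mrsurv_rank_error")
  }
  iz <- seq_len(ncol(z)) + 1L
  Vz <- s1$sigma2 * s1$xtx_inv[iz, iz, drop = FALSE]
  Fstat <- as.numeric(t(s1$beta[iz]) %*% solve(Vz, s1$beta[iz])) / length(iz)
  df2 <- if (is.null(C)) data.frame(exposure = exposure, cf_residual = v)
         else data.frame(exposure = exposure, cf_residual = v, C)
  sv <- survival::Surv(time, as.integer(event))
  fml <- stats::as.formula(paste("sv ~", paste(colnames(df2), collapse = " + ")))
  cox <- survival::coxph(fml, data = df2, ties = ties)
  if (!is.finite(cox$loglik[2]) || any(!is.finite(cox$coefficients))) {
    stop_mrsurv("stage-2 Cox partial likelihood did not converge",
                class = "mrsurv_convergence_error")
  }
  b <- cox$coefficients
  se <- stats::setNames(sqrt(diag(cox$var)), names(b))
  zq <- stats::qnorm(0.975)
  structure(list(
    log_hr = unname(b["exposure"]), se = unname(se["exposure"]),
    hr = exp(unname(b["exposure"])),
    ci = exp(unname(b["exposure"]) + c(-1, 1) * zq * unname(se["exposure"])),
    ci_method = "wald",
    resid_coef = unname(b["cf_residual"]), resid_se = unname(se["cf_residual"]),
    resid_p = 2 * stats::pnorm(-abs(unname(b["cf_residual"] / se["cf_residual"]))),
    first_stage_F = Fstat, ties = ties, n = length(time),
    n_events = sum(as.integer(event)),
    stage1_residuals = v, cox = cox,
    covariate_label = if (is.null(C)) "none" else paste(colnames(C), collapse = "+")
  ), class = "tsri_fit")
}

#' Subject-level bootstrap CI for the two-stage residual inclusion HR
#'
#' Nonparametric bootstrap re-running both stages on resampled subjects;
#' percentile interval; deterministic under a fixed seed.
#'
#' @inheritParams fit_2sri_cox
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List with `ci` (HR scale), `ci_log_hr`, `n_boot_used`.
#' @export
tsri_bootstrap_ci <- function(time, event, exposure, instrument,
                              covariates = NULL, n_boot = 500, seed = 1,
                              level = 0.95, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (n_boot < 100) {
    stop_mrsurv("n_boot must be >= 100", class = "mrsurv_parameter_error")
  }
  z <- as.matrix(instrument)
  C <- design_matrix(covariates, length(exposure))
  set.seed(derive_seed(seed, "tsri_bootstrap"))
  n <- length(time)
  est <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    est[b] <- tryCatch({
      fit <- fit_2sri_cox(time[idx], event[idx], exposure[idx],
                          z[idx, , drop = FALSE],
                          if (is.null(C)) NULL else C[idx, , drop = FALSE],
                          ties = ties)
      fit$log_hr
    }, error = function(e) NA_real_)
  }
  fail <- mean(is.na(est))
  if (fail > 0.2) {
    stop_mrsurv("%.0f%% of bootstrap replicates failed to converge", 100 * fail,
                class = "mrsurv_convergence_error")
  }
  qs <- stats::quantile(est, c((1 - level) / 2, (1 + level) / 2), na.rm = TRUE)
  list(ci = exp(unname(qs)), ci_log_hr = unname(qs),
       n_boot_used = sum(!is.na(est)), level = level)
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("%s estimate (adjusted for: %s)\n",
              toupper(x$estimator), x$covariate_label))
  cat(sprintf("  beta = %.4f  SE = %.4f  P = %.4g  (n = %d)\n",
              x$beta, x$se, x$p, x$n))
  if (is.finite(x$first_stage_F)) {
    cat(sprintf("  first-stage F = %.2f\n", x$first_stage_F))
  }
  if (is.finite(x$dwh_p)) cat(sprintf("  P_DWH = %.4g\n", x$dwh_p))
  invisible(x)
}

#' @export
summary.iv_fit <- function(object, ...) object$coefficients

#' @export
coef.iv_fit <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
confint.iv_fit <- function(object, parm = "exposure", level = 0.95, ...) {
  tq <- stats::qt((1 + level) / 2, object$df)
  ct <- object$coefficients
  i <- match(parm, ct$term)
  cbind(lower = ct$beta[i] - tq * ct$se[i], upper = ct$beta[i] + tq * ct$se[i])
}

#' @export
print.tsri_fit <- function(x, ...) {
  cat("Two-stage residual inclusion (control function) Cox estimator\n")
  cat(sprintf("  causal HR per exposure unit = %.3f  (95%% CI %.3f-%.3f, %s)\n",
              x$hr, x$ci[1], x$ci[2], x$ci_method))
  cat(sprintf("  residual term p = %.4g (endogeneity diagnostic)\n", x$resid_p))
  cat(sprintf("  first-stage F = %.2f; n = %d, events = %d; ties = %s\n",
              x$first_stage_F, x$n, x$n_events, x$ties))
  invisible(x)
}

#' @export
coef.tsri_fit <- function(object, ...) {
  c(log_hr = object$log_hr, cf_residual = object$resid_coef)
}

#' @export
confint.tsri_fit <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm((1 + level) / 2)
  matrix(object$log_hr + c(-1, 1) * zq * object$se, nrow = 1,
         dimnames = list("log_hr", c("lower", "upper")))
}
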