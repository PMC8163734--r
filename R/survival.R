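# Cox proportional-hazards fitting with the named covariate-set presets,
# Kaplan-Meier / log-rank, a supremum-type proportional-hazards test based
# on multiplier resampling of the score process, and covariate-adjusted
# survival curves.

Z95 <- 1.959964  # fixed 95% normal quantile used for all reported CIs

#' Covariate-set presets for the Cox models
#'
#' `model1`: age, sex, smoking. `model2`: model1 plus baseline SBP/DBP,
#' BMI, waist, hemoglobin, platelet, HbA1c, ALT, gamma-GT, triglyceride and
#' HDL. `model3`: model2 plus albumin. Names refer to columns of the
#' derived cohort.
#'
#' @param preset `"model1"`, `"model2"` or `"model3"`.
#' @return Character vector of covariate column names.
#' @export
cox_preset <- function(preset = c("model1", "model2", "model3")) {
  preset <- match.arg(preset)
  m1 <- c("age", "male", "smoker")
  m2 <- c(m1, "baseline_sbp", "baseline_dbp", "bmi", "waist", "hemoglobin",
          "platelet", "hba1c", "alt", "ggt", "tg", "hdl")
  switch(preset, model1 = m1, model2 = m2, model3 = c(m2, "albumin"))
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the partial likelihood via
#' [survival::coxph()], with Wald standard errors from the observed
#' information and 95% CIs `exp(coef +/- 1.959964 * SE)`. The covariate
#' sets of the named presets can be augmented with extra columns (e.g. a
#' coded genotype).
#'
#' @param data Data frame containing the time/event columns and covariates
#'   (e.g. derived `participants`).
#' @param covariates Character vector of covariate column names, or a
#'   preset name via `preset`.
#' @param preset Optional preset (see [cox_preset()]); `covariates` are
#'   appended to it.
#' @param ties `"breslow"` (default, mirroring conventional SAS PHREG
#'   output) or `"efron"`.
#' @param time_col,event_col Column names for follow-up time (months) and
#'   event indicator.
#' @param ... Passed to [survival::coxph()] (e.g. `control`).
#' @return A `cox_fit` object.
#' @export
fit_cox <- function(data, covariates = NULL, preset = NULL,
                    ties = c("breslow", "efron"),
                    time_col = "time_month", event_col = "event", ...) {
  ties <- match.arg(ties)
  covs <- c(if (!is.null(preset)) cox_preset(preset), covariates)
  covs <- unique(covs)
  if (length(covs) < 1) {
    stop_mrsurv("at least one covariate required", class = "mrsurv_parameter_error")
  }
  miss <- setdiff(c(covs, time_col, event_col), names(data))
  if (length(miss) > 0) {
    stop_mrsurv("column(s) absent from data: %s", paste(miss, collapse = ", "),
                class = "mrsurv_parameter_error")
  }
  d <- data[stats::complete.cases(data[, c(time_col, event_col, covs)]), , drop = FALSE]
  ev <- as.integer(d[[event_col]])
  if (sum(ev) < 1) {
    stop_mrsurv("no events in the analysis sample", class = "mrsurv_parameter_error")
  }
  const <- covs[vapply(covs, function(cl) {
    x <- d[[cl]]
    is.numeric(x) && stats::sd(x) == 0
  }, logical(1))]
  if (length(const) > 0) {
    stop_mrsurv("constant covariate(s): %s", paste(const, collapse = ", "),
                class = "mrsurv_rank_error")
  }
  fml <- stats::as.formula(paste("survival::Surv(", time_col, ",", event_col, ") ~",
                                 paste(covs, collapse = " + ")))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties, ...),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  b <- fit$coefficients
  se <- sqrt(diag(fit$var))
  diverged <- any(grepl("infinite|out of range|did not converge", warns)) ||
    any(!is.finite(b)) || any(abs(b) > 15 & se > 100)
  if (diverged) {
    stop_mrsurv("monotone partial likelihood (no finite MLE); diagnostics: %s",
                paste(unique(warns), collapse = "; "),
                class = "mrsurv_convergence_error")
  }
  tab <- data.frame(
    term = names(b), coef = unname(b), se = unname(se),
    hr = exp(unname(b)),
    ci_lower = exp(unname(b) - Z95 * unname(se)),
    ci_upper = exp(unname(b) + Z95 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(b) / unname(se))),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = tab, loglik = fit$loglik, ties = ties,
                 n = nrow(d), n_events = sum(ev), covariates = covs,
                 time_col = time_col, event_col = event_col,
                 fit = fit, data = d, warnings = warns),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tb <- x$coefficients
  tb$`HR (95% CI)` <- sprintf("%.3f (%s)", tb$hr, fmt_ci(tb$ci_lower, tb$ci_upper))
  print(tb[, c("term", "HR (95% CI)", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$coefficients$coef, object$coefficients$term)
}

#' @export
summary.cox_fit <- function(object, ...) object$coefficients

#' Kaplan-Meier product-limit curves
#'
#' Product-limit estimate per group with Greenwood pointwise variance.
#'
#' @param time,event Survival data (months; 0/1 indicator).
#' @param group Optional grouping vector (one curve per level).
#' @return A `km_curve`: list of per-group data frames with columns
#'   time, n_risk, n_event, n_censor, survival, greenwood_se.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  if (any(table(group) < 1)) {
    stop_mrsurv("each group needs at least one subject",
                class = "mrsurv_parameter_error")
  }
  out <- lapply(levels(group), function(gl) {
    i <- group == gl
    sf <- survival::survfit(survival::Surv(time[i], as.integer(event[i])) ~ 1)
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               n_censor = sf$n.censor, survival = sf$surv,
               greenwood_se = sf$surv * sf$std.err)
  })
  names(out) <- levels(group)
  structure(out, class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  for (g in names(x)) {
    cat(sprintf("group %s: %d time points, final survival %.3f\n",
                g, nrow(x[[g]]), utils::tail(x[[g]]$survival, 1)))
  }
  invisible(x)
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank statistic with
#' `df = groups - 1`.
#'
#' @param time,event,group As in [kaplan_meier()].
#' @return List with `chisq`, `df`, `p`.
#' @export
log_rank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2) {
    stop_mrsurv("log-rank requires at least two groups",
                class = "mrsurv_parameter_error")
  }
  sd_ <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- nlevels(group) - 1
  list(chisq = sd_$chisq, df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Supremum test of the proportional-hazards assumption
#'
#' Kolmogorov-type supremum of the cumulative score process per covariate,
#' with p-values obtained by Gaussian-multiplier resampling of the
#' process (the observed-information correction for estimating the
#' regression coefficients is included). Deterministic under a fixed seed.
#'
#' @param fit A `cox_fit`.
#' @param n_resample Number of multiplier resamples (>= 100).
#' @param seed Integer seed.
#' @return Data frame: term, sup_statistic (standardized by the square
#'   root of the terminal information), p.
#' @export
ph_supremum_test <- function(fit, n_resample = 1000, seed = 1) {
  if (!inherits(fit, "cox_fit")) {
    stop_mrsurv("fit must be a cox_fit", class = "mrsurv_parameter_error")
  }
  if (n_resample < 100) {
    stop_mrsurv("n_resample must be >= 100", class = "mrsurv_parameter_error")
  }
  d <- fit$data
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(fit$covariates, collapse = "+"))),
    data = d)[, -1, drop = FALSE]
  beta <- coef(fit)
  time <- d[[fit$time_col]]
  ev <- as.integer(d[[fit$event_col]])
  n <- nrow(X); p <- ncol(X)
  r <- as.numeric(exp(X %*% beta))
  tk <- sort(unique(time[ev == 1]))
  K <- length(tk)

  S0 <- numeric(K); xbar <- matrix(0, K, p); dk <- numeric(K)
  Vsum <- array(0, dim = c(p, p, K))
  Iacc <- matrix(0, p, p)
  for (k in seq_len(K)) {
    at <- time >= tk[k]
    rw <- r[at]
    S0[k] <- sum(rw)
    Xk <- X[at, , drop = FALSE]
    xb <- colSums(Xk * rw) / S0[k]
    xbar[k, ] <- xb
    dk[k] <- sum(ev == 1 & time == tk[k])
    Vk <- crossprod(Xk * sqrt(rw)) / S0[k] - tcrossprod(xb)
    Iacc <- Iacc + Vk * dk[k]
    Vsum[, , k] <- Iacc
  }
  I_tau <- Iacc
  dL <- dk / S0

  # per-subject score-residual processes, one n x K matrix per covariate
  Smats <- vector("list", p)
  dN <- outer(time, tk, function(a, b) as.numeric(a == b)) * ev
  Y <- outer(time, tk, ">=")
  dM <- dN - Y * (r %o% dL)
  for (j in seq_len(p)) {
    A <- (matrix(X[, j], n, K) - matrix(xbar[, j], n, K, byrow = TRUE)) * dM
    Smats[[j]] <- t(apply(A, 1, cumsum))
    if (K == 1) Smats[[j]] <- matrix(A, n, 1)
  }
  W_obs <- vapply(Smats, colSums, numeric(K))          # K x p
  if (K == 1) W_obs <- matrix(W_obs, 1, p)
  sd_tau <- sqrt(pmax(diag(I_tau), .Machine$double.eps))
  obs_sup <- apply(abs(W_obs), 2, max) / sd_tau

  set.seed(derive_seed(seed, "ph_supremum"))
  I_tau_inv <- solve(I_tau)
  s_tau <- vapply(Smats, function(S) S[, K], numeric(n)) # n x p
  exceed <- numeric(p)
  for (b in seq_len(n_resample)) {
    G <- stats::rnorm(n)
    g_tau <- as.numeric(crossprod(s_tau, G))           # p
    corr_coef <- I_tau_inv %*% g_tau                   # p
    for (j in seq_len(p)) {
      Wb <- as.numeric(crossprod(Smats[[j]], G))       # K
      # correction: I(t) %*% I(tau)^-1 %*% g_tau, component j
      corr <- vapply(seq_len(K), function(k) {
        sum(Vsum[j, , k] * corr_coef)
      }, numeric(1))
      sup_b <- max(abs(Wb - corr)) / sd_tau[j]
      if (sup_b >= obs_sup[j]) exceed[j] <- exceed[j] + 1
    }
  }
  data.frame(term = colnames(X), sup_statistic = obs_sup,
             p = (exceed + 1) / (n_resample + 1),
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted survival curves from a Cox fit
#'
#' `S(t | x) = exp(-Lambda0(t) * exp(x' beta))` with the Breslow baseline
#' cumulative hazard. Each requested stratum fixes the named covariates;
#' the remaining covariates sit at the analysis-sample means
#' (reference-population adjustment).
#'
#' @param fit A `cox_fit`.
#' @param strata Data frame, one row per stratum, columns a subset of the
#'   fitted covariates; a `label` column is used for naming if present.
#' @return Long data frame: stratum, time, survival.
#' @export
adjusted_survival_curves <- function(fit, strata) {
  strata <- as.data.frame(strata)
  labs <- if ("label" %in% names(strata)) strata$label else
    apply(strata, 1, function(r) paste(names(strata), r, sep = "=", collapse = ","))
  strata$label <- NULL
  unknown <- setdiff(names(strata), fit$covariates)
  if (length(unknown) > 0) {
    stop_mrsurv("stratum covariate(s) not in the fitted model: %s",
                paste(unknown, collapse = ", "), class = "mrsurv_parameter_error")
  }
  bh <- survival::basehaz(fit$fit, centered = FALSE)
  beta <- coef(fit)
  d <- fit$data
  base_vals <- vapply(fit$covariates, function(cl) mean(as.numeric(d[[cl]])),
                      numeric(1))
  out <- lapply(seq_len(nrow(strata)), function(i) {
    vals <- base_vals
    for (cl in names(strata)) vals[cl] <- as.numeric(strata[i, cl])
    lp <- sum(beta[fit$covariates] * vals[fit$covariates])
    data.frame(stratum = labs[i], time = bh$time,
               survival = exp(-bh$hazard * exp(lp)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
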