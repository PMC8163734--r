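# Restricted cubic splines (natural splines in the restricted
# truncated-power parameterization): basis construction, linear and Cox
# spline regressions centred at a reference exposure, and a Wald test of
# nonlinearity.

#' Default restricted-cubic-spline knots
#'
#' Four knots at the 5th/35th/65th/95th percentiles of the exposure.
#'
#' @param x Exposure vector.
#' @param probs Percentile positions.
#' @return Numeric knot vector.
#' @export
rcs_knots <- function(x, probs = c(0.05, 0.35, 0.65, 0.95)) {
  as.numeric(stats::quantile(x, probs, na.rm = TRUE, names = FALSE))
}

#' Restricted cubic spline basis
#'
#' The restricted truncated-power construction: for knots
#' `t1 < ... < tk` the basis has `k - 1` columns — the linear term `x` and
#' `k - 2` restricted cubic terms
#' `[(x - tj)+^3 - (x - t(k-1))+^3 (tk - tj)/(tk - t(k-1))
#'   + (x - tk)+^3 (t(k-1) - tj)/(tk - t(k-1))] / (tk - t1)^2`,
#' scaled for conditioning. The basis is exactly linear for `x <= t1` and
#' `x >= tk`.
#'
#' @param x Evaluation points.
#' @param knots At least 3 distinct knots, within the data range for
#'   fitting.
#' @return Matrix with columns `x`, `s1`, ..., `s(k-2)`; attributes
#'   `knots` and `scale`.
#' @export
#' @examples
#' b <- rcs_basis(seq(1, 4, 0.5), knots = c(1, 2, 3, 4))
#' colnames(b)
rcs_basis <- function(x, knots) {
  knots <- sort(as.numeric(knots))
  if (length(knots) < 3 || anyDuplicated(knots)) {
    stop_mrsurv("need >= 3 distinct knots", class = "mrsurv_parameter_error")
  }
  k <- length(knots)
  t1 <- knots[1]; tk <- knots[k]; tk1 <- knots[k - 1]
  scale <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    B[, j + 1] <- (pos3(x - tj) -
                     pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                     pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / scale
  }
  colnames(B) <- c("x", paste0("s", seq_len(k - 2)))
  attr(B, "knots") <- knots
  attr(B, "scale") <- scale
  B
}

rcs_default_grid <- function(x, n = 100) {
  r <- stats::quantile(x, c(0.01, 0.99), na.rm = TRUE, names = FALSE)
  seq(r[1], r[2], length.out = n)
}

new_rcs_curve <- function(curve, reference, knots, scale_label, gamma, vcov_g,
                          df_resid = NA_integer_, model = NULL) {
  structure(list(curve = curve, reference = reference, knots = knots,
                 scale = scale_label, gamma = gamma, vcov = vcov_g,
                 df_resid = df_resid, model = model),
            class = "rcs_curve")
}

#' @export
print.rcs_curve <- function(x, ...) {
  cat(sprintf("Restricted cubic spline curve (%s scale), %d knots at %s\n",
              x$scale, length(x$knots),
              paste(format(round(x$knots, 3)), collapse = ", ")))
  cat(sprintf("  reference exposure: %s; grid of %d points\n",
              format(x$reference), nrow(x$curve)))
  invisible(x)
}

# contrast rows for effect(x) - effect(ref) over a grid
rcs_contrast <- function(grid, reference, knots) {
  rcs_basis(grid, knots) - matrix(rcs_basis(reference, knots), nrow = length(grid),
                                  ncol = length(knots) - 1, byrow = TRUE)
}

#' Linear-outcome restricted cubic spline curve
#'
#' OLS of the outcome (e.g. BP change, mmHg/month) on the spline basis of
#' the exposure plus covariates. The returned curve is the fitted spline
#' effect minus its value at the reference exposure, so it passes exactly
#' through zero at the reference, with pointwise delta-method 95% CIs
#' (width zero at the reference).
#'
#' @param outcome,exposure Numeric vectors.
#' @param covariates Optional data frame / matrix.
#' @param knots Knot vector (default [rcs_knots()] of the exposure).
#' @param reference Reference exposure value (default 4.0 g/dL).
#' @param grid Evaluation grid (default 100 points over the inner 98% of
#'   the exposure).
#' @return An `rcs_curve` (difference scale).
#' @export
fit_rcs_linear <- function(outcome, exposure, covariates = NULL, knots = NULL,
                           reference = 4.0, grid = NULL) {
  cc <- stats::complete.cases(outcome, exposure) &
    (if (is.null(covariates)) TRUE else stats::complete.cases(covariates))
  y <- outcome[cc]; x <- exposure[cc]
  C <- design_matrix(if (is.null(covariates)) NULL else
    as.data.frame(covariates)[cc, , drop = FALSE], length(y))
  if (is.null(knots)) knots <- rcs_knots(x)
  if (reference < min(knots) || reference > max(knots)) {
    warning("reference outside the knot span; curve extrapolates there")
  }
  B <- rcs_basis(x, knots)
  X <- cbind(`(Intercept)` = 1, B, C)
  f <- ols_core(y, X)
  if (is.null(grid)) grid <- sort(unique(c(rcs_default_grid(x), reference)))
  ib <- seq_len(ncol(B)) + 1L
  gam <- f$beta[ib]
  Vg <- f$sigma2 * f$xtx_inv[ib, ib, drop = FALSE]
  Cm <- rcs_contrast(grid, reference, knots)
  eff <- as.numeric(Cm %*% gam)
  se <- sqrt(pmax(rowSums((Cm %*% Vg) * Cm), 0))
  curve <- data.frame(exposure = grid, effect = eff,
                      lower = eff - Z95 * se, upper = eff + Z95 * se)
  new_rcs_curve(curve, reference, knots, "difference", gam, Vg,
                df_resid = f$df, model = list(type = "linear"))
}

#' Cox restricted cubic spline hazard-ratio curve
#'
#' Cox model on the spline basis of the exposure plus covariates;
#' `HR(x) = exp(spline(x) - spline(reference))`, exactly 1 at the
#' reference, with pointwise delta-method CIs on the log scale.
#'
#' @param time,event Survival data (months; indicator).
#' @param exposure Numeric exposure (albumin, g/dL).
#' @param covariates Optional covariates.
#' @param knots,reference,grid As in [fit_rcs_linear()].
#' @param ties Cox ties method.
#' @return An `rcs_curve` (hazard-ratio scale; `curve$effect` is the HR).
#' @export
fit_rcs_cox <- function(time, event, exposure, covariates = NULL, knots = NULL,
                        reference = 4.0, grid = NULL,
                        ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  cc <- stats::complete.cases(time, event, exposure) &
    (if (is.null(covariates)) TRUE else stats::complete.cases(covariates))
  tt <- time[cc]; ev <- as.integer(event[cc]); x <- exposure[cc]
  C <- design_matrix(if (is.null(covariates)) NULL else
    as.data.frame(covariates)[cc, , drop = FALSE], length(x))
  if (is.null(knots)) knots <- rcs_knots(x)
  B <- rcs_basis(x, knots)
  d <- data.frame(B, check.names = FALSE)
  if (!is.null(C)) d <- cbind(d, C)
  sv <- survival::Surv(tt, ev)
  fml <- stats::as.formula(paste("sv ~", paste(sprintf("`%s`", colnames(d)),
                                               collapse = " + ")))
  cox <- survival::coxph(fml, data = d, ties = ties)
  ib <- seq_len(ncol(B))
  gam <- cox$coefficients[ib]
  Vg <- cox$var[ib, ib, drop = FALSE]
  if (is.null(grid)) grid <- sort(unique(c(rcs_default_grid(x), reference)))
  Cm <- rcs_contrast(grid, reference, knots)
  lhr <- as.numeric(Cm %*% gam)
  se <- sqrt(pmax(rowSums((Cm %*% Vg) * Cm), 0))
  curve <- data.frame(exposure = grid, effect = exp(lhr),
                      lower = exp(lhr - Z95 * se), upper = exp(lhr + Z95 * se))
  new_rcs_curve(curve, reference, knots, "hazard-ratio", gam, Vg,
                model = list(type = "cox", fit = cox))
}

#' Wald test of nonlinearity for a fitted spline curve
#'
#' Tests that all `k - 2` nonlinear spline coefficients are zero. For
#' linear-outcome fits an exact F-test is used (statistic compared to
#' `F(k-2, df_resid)`); for Cox fits a chi-square Wald test.
#'
#' @param fit An `rcs_curve`.
#' @return List with `statistic`, `df`, `p`.
#' @export
nonlinearity_test <- function(fit) {
  k <- length(fit$knots)
  inl <- seq(2, k - 1)         # nonlinear columns of the basis
  g <- fit$gamma[inl]
  V <- fit$vcov[inl, inl, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) {
    return(list(statistic = NA_real_, df = length(inl), p = NA_real_,
                applicable = FALSE))
  }
  W <- as.numeric(t(g) %*% Vi %*% g)
  df <- length(inl)
  if (identical(fit$model$type, "linear") && is.finite(fit$df_resid)) {
    Fstat <- W / df
    list(statistic = Fstat, df = df,
         p = stats::pf(Fstat, df, fit$df_resid, lower.tail = FALSE),
         applicable = TRUE)
  } else {
    list(statistic = W, df = df,
         p = stats::pchisq(W, df, lower.tail = FALSE), applicable = TRUE)
  }
}
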