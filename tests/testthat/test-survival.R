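# Cox fitting against a brute-force partial-likelihood oracle, KM and
# log-rank against hand bookkeeping, the PH supremum test, and adjusted
# survival curves.

tiefree_fixture <- function(seed, n = 10) {
  set.seed(seed)
  x <- rnorm(n)
  tm <- sort(rexp(n, 0.05)) + seq(0.001, 0.01, length.out = n)  # distinct
  ev <- rbinom(n, 1, 0.7)
  if (sum(ev) == 0) ev[1] <- 1
  data.frame(time_month = sample(tm), event = ev, x = x)
}

test_that("Cox coefficient matches brute-force partial-likelihood maximization", {
  for (s in 1:5) {
    d <- tiefree_fixture(100 + s)
    fit <- fit_cox(d, covariates = "x")
    b_oracle <- oracle_cox_coef(d$time_month, d$event, d$x)
    expect_lt(abs(coef(fit)["x"] - b_oracle), 1e-4,
              label = sprintf("fixture %d", s))
  }
})

test_that("Breslow and Efron coincide on tie-free data", {
  d <- tiefree_fixture(7, n = 40)
  fb <- fit_cox(d, covariates = "x", ties = "breslow")
  fe <- fit_cox(d, covariates = "x", ties = "efron")
  expect_equal(coef(fb), coef(fe), tolerance = 1e-10)
  expect_equal(fb$coefficients$se, fe$coefficients$se, tolerance = 1e-10)
})

test_that("monotone likelihood and degenerate inputs raise typed errors", {
  d <- data.frame(time_month = c(1, 2), event = c(1, 0), x = c(1, 0))
  expect_error(fit_cox(d, covariates = "x"),
               class = "mrsurv_convergence_error")
  d2 <- data.frame(time_month = c(1, 2, 3), event = c(1, 1, 0), x = 1)
  expect_error(fit_cox(d2, covariates = "x"), class = "mrsurv_rank_error")
  d3 <- data.frame(time_month = 1:3, event = 0, x = rnorm(3))
  expect_error(fit_cox(d3, covariates = "x"), class = "mrsurv_parameter_error")
})

test_that("Cox coefficients rescale with affine covariate rescaling", {
  d <- tiefree_fixture(9, n = 60)
  f1 <- fit_cox(d, covariates = "x")
  d$x2 <- 10 * d$x + 3
  f2 <- fit_cox(d, covariates = "x2")
  expect_equal(unname(coef(f1)["x"]), unname(10 * coef(f2)["x2"]),
               tolerance = 1e-6)
})

test_that("simulation recovery: mean Cox estimate near the true log hazard ratio", {
  b_true <- -0.4
  est <- numeric(50)
  for (r in 1:50) {
    set.seed(300 + r)
    n <- 800
    x <- rnorm(n, 0, 1)
    tm <- rexp(n, 0.01 * exp(b_true * x))
    cens <- runif(n, 20, 200)
    d <- data.frame(time_month = pmin(tm, cens), event = as.integer(tm <= cens),
                    x = x)
    est[r] <- coef(fit_cox(d, covariates = "x", ties = "efron"))["x"]
  }
  expect_lt(abs(mean(est) - b_true) / abs(b_true), 0.05)
})

test_that("Kaplan-Meier matches the product-limit construction", {
  # all events, distinct times -> steps 0.75, 0.5, 0.25, 0
  km <- kaplan_meier(c(3, 1, 4, 2), c(1, 1, 1, 1))
  expect_equal(km$all$survival, c(0.75, 0.5, 0.25, 0))

  # all censored -> survival constant 1
  km0 <- kaplan_meier(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(km0$all$survival == 1))

  # interleaved censoring vs explicit risk-set oracle
  tm <- c(2, 3, 3, 5, 6, 8, 11, 11, 12, 14)
  ev <- c(1, 0, 1, 1, 0, 1, 0, 1, 0, 0)
  km2 <- kaplan_meier(tm, ev)
  orc <- oracle_km(tm, ev)
  got <- km2$all[km2$all$n_event > 0, c("time", "survival")]
  rownames(got) <- NULL
  expect_equal(got, orc, tolerance = 1e-12)

  # Greenwood variance positive where events occurred
  expect_true(all(km2$all$greenwood_se[km2$all$n_event > 0] > 0))
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(17)
  tm <- sample(1:50, 25, replace = FALSE)
  km <- kaplan_meier(tm, rep(1, 25))
  emp <- vapply(km$all$time, function(t) mean(tm > t), numeric(1))
  expect_equal(km$all$survival, emp, tolerance = 1e-12)
})

test_that("log-rank: symmetry zero, hand-computed oracle, permutation consistency", {
  tm <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- c(1, 0, 1, 1, 1, 0, 1, 1)
  gr <- rep(c("a", "b"), each = 4)
  lr <- log_rank_test(tm, ev, gr)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  expect_error(log_rank_test(tm, ev, rep("a", 8)),
               class = "mrsurv_parameter_error")

  tm2 <- c(2, 4, 6, 9, 3, 5, 8, 12)
  ev2 <- c(1, 1, 0, 1, 1, 1, 1, 0)
  gr2 <- rep(c("a", "b"), each = 4)
  lr2 <- log_rank_test(tm2, ev2, gr2)
  expect_equal(lr2$chisq, oracle_logrank(tm2, ev2, gr2), tolerance = 1e-10)

  # permutation reference distribution agrees with the asymptotic p
  set.seed(23)
  n <- 60
  grp <- rep(c(0, 1), each = n / 2)
  tms <- rexp(n, ifelse(grp == 1, 0.05, 0.02))
  evs <- rep(1, n)
  obs <- log_rank_test(tms, evs, grp)$chisq
  perm <- replicate(1000, log_rank_test(tms, evs, sample(grp))$chisq)
  p_perm <- mean(perm >= obs)
  p_asym <- pchisq(obs, 1, lower.tail = FALSE)
  expect_lt(abs(p_perm - p_asym), 3 * sqrt(p_asym * (1 - p_asym) / 1000) + 0.01)
})

test_that("PH supremum test is seed-deterministic and rejects strong non-PH", {
  qc <- quick_cohort(n = 300, seed = 71)
  fit <- fit_cox(qc$participants, covariates = "albumin", preset = "model1")
  p1 <- ph_supremum_test(fit, n_resample = 200, seed = 5)
  p2 <- ph_supremum_test(fit, n_resample = 200, seed = 5)
  expect_identical(p1, p2)
  expect_error(ph_supremum_test(fit, n_resample = 50),
               class = "mrsurv_parameter_error")

  # crossing-hazards violation (effect reverses sign mid-follow-up) on
  # grid-recorded times; the score drift must dominate the resampled sups
  hits <- 0
  for (r in 1:20) {
    set.seed(400 + r)
    n <- 8000
    x <- rbinom(n, 1, 0.5)
    t1 <- rexp(n, 0.08 * exp(1.5 * x))     # early: strong positive effect
    t2 <- 15 + rexp(n, 0.08 * exp(-1.5 * x))
    tm <- ifelse(t1 < 15, t1, t2)
    tmg <- pmin(5 * ceiling(tm / 5), 40)
    d <- data.frame(time_month = tmg, event = as.integer(tm <= 40), x = x)
    f <- fit_cox(d, covariates = "x")
    pv <- ph_supremum_test(f, n_resample = 200, seed = r)$p
    if (pv < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.8)
})

test_that("PH supremum test keeps near-nominal size under exact PH", {
  rej <- 0
  for (r in 1:40) {
    set.seed(500 + r)
    n <- 200
    x <- rnorm(n)
    tm <- rexp(n, 0.03 * exp(0.3 * x))
    d <- data.frame(time_month = pmin(tm, 60),
                    event = as.integer(tm <= 60), x = x)
    f <- fit_cox(d, covariates = "x")
    if (ph_supremum_test(f, n_resample = 200, seed = r)$p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / 40, 0.10)
})

test_that("adjusted survival curves are proper and ordered by the linear predictor", {
  qc <- quick_cohort(n = 500, seed = 81)
  fit <- fit_cox(qc$participants, covariates = "albumin", preset = "model1")
  cur <- adjusted_survival_curves(
    fit, data.frame(albumin = c(3.8, 4.4),
                    label = c("low", "high")))
  for (g in c("low", "high")) {
    s <- cur$survival[cur$stratum == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s <= 1 & s >= 0))
  }
  # albumin coefficient is negative: higher albumin -> higher survival
  b_alb <- coef(fit)["albumin"]
  s_lo <- cur$survival[cur$stratum == "low"]
  s_hi <- cur$survival[cur$stratum == "high"]
  if (b_alb < 0) expect_true(all(s_hi >= s_lo - 1e-12))
  expect_error(adjusted_survival_curves(fit, data.frame(nope = 1)),
               class = "mrsurv_parameter_error")
})

test_that("beta = 0 adjusted curve equals the Nelson-Aalen transform", {
  set.seed(91)
  n <- 120
  d <- data.frame(time_month = rexp(n, 0.04), event = rbinom(n, 1, 0.7),
                  x = rnorm(n))
  fit <- fit_cox(d, covariates = "x",
                 control = survival::coxph.control(iter.max = 0), init = 0)
  cur <- adjusted_survival_curves(fit, data.frame(x = 0, label = "ref"))
  # Nelson-Aalen by explicit risk sets
  tt <- sort(unique(d$time_month[d$event == 1]))
  na_ <- cumsum(vapply(tt, function(t)
    sum(d$time_month == t & d$event == 1) / sum(d$time_month >= t), numeric(1)))
  s_at <- approx(cur$time, cur$survival, xout = tt, method = "constant",
                 f = 0)$y
  expect_equal(s_at, exp(-na_), tolerance = 1e-8)
})

test_that("partial likelihood at the fit is a local maximum", {
  d <- tiefree_fixture(13, n = 50)
  fit <- fit_cox(d, covariates = "x")
  b <- unname(coef(fit)["x"])
  pl <- function(bv) {
    eta <- bv * d$x
    s <- 0
    for (i in seq_len(nrow(d))) {
      if (d$event[i] == 1) {
        s <- s + eta[i] - log(sum(exp(eta[d$time_month >= d$time_month[i]])))
      }
    }
    s
  }
  expect_gte(pl(b), pl(b + 1e-3) - 1e-12)
  expect_gte(pl(b), pl(b - 1e-3) - 1e-12)
})
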