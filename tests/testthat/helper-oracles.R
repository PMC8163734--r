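# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct formula evaluation, exhaustive
# enumeration, or generic numeric optimization.

# Hardy-Weinberg exact test by direct evaluation of the conditional
# probability of each heterozygote count given the allele counts,
# P(het = h | n, n_minor) = n! 2^h n_minor! n_major! / (nAA! h! naa! (2n)!),
# summing configurations no more probable than the observed one.
oracle_hwe <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  n_minor <- 2 * n_hom_minor + n_het
  n_major <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, min(n_minor, n_major), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (n_minor - h) / 2
    nAA <- n - naa - h
    lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(n_major + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  sum(p[p <= obs * (1 + 1e-10)])
}

# Breslow-type log partial likelihood for a single covariate (no ties in
# the fixtures it is used on), maximized by generic 1-d optimization.
oracle_cox_coef <- function(time, event, x, interval = c(-8, 8)) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  nll <- function(b) {
    eta <- b * x
    s <- 0
    for (i in seq_along(time)) {
      if (event[i] == 1) {
        risk <- time >= time[i]
        s <- s - (eta[i] - log(sum(exp(eta[risk]))))
      }
    }
    s
  }
  stats::optimize(nll, interval = interval, tol = 1e-9)$minimum
}

# negative log-likelihood (+ gradient) of a logistic regression, for
# optim-based fits
oracle_logistic_nll <- function(beta, X, y) {
  eta <- as.numeric(X %*% beta)
  -sum(y * eta - log1p(exp(eta)))
}
oracle_logistic_grad <- function(beta, X, y) {
  eta <- as.numeric(X %*% beta)
  -as.numeric(crossprod(X, y - stats::plogis(eta)))
}

# Product-limit estimator computed by explicit risk-set bookkeeping.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (k in seq_along(tt)) {
    n_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = tt, survival = surv)
}

# Two-group log-rank O-E/V by explicit hypergeometric bookkeeping.
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  tt <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (k in seq_along(tt)) {
    at <- time >= tt[k]
    n <- sum(at); n1 <- sum(at & group == g1)
    d <- sum(time == tt[k] & event == 1)
    d1 <- sum(time == tt[k] & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# restricted truncated-power nonlinear basis term, straight from the
# formula, for cross-checking the basis construction
oracle_rcs_term <- function(x, knots, j) {
  k <- length(knots)
  tj <- knots[j]; tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  pp <- function(u) pmax(u, 0)^3
  (pp(x - tj) - pp(x - tk1) * (tk - tj) / (tk - tk1) +
     pp(x - tk) * (tk1 - tj) / (tk - tk1)) / (tk - t1)^2
}

# small in-memory cohort for fast unit tests
quick_cohort <- function(n = 400, seed = 11, n_null_snps = 5, ...) {
  cfg <- sim_config(n_subjects = n, n_null_snps = n_null_snps, seed = seed, ...)
  gen <- generate_cohort(cfg)
  ph <- gen$phenotype
  coh <- derive_cohort(list(
    participants = ph[!duplicated(ph$subject_id),
                      setdiff(names(ph), c("visit_month", "sbp", "dbp", "med_flag"))],
    visits = ph[, c("subject_id", "visit_month", "sbp", "dbp", "med_flag")]))
  list(cohort = coh, participants = coh$participants, gen = gen, config = cfg)
}

write_test_vcf <- function(path, ids, gts) {
  # gts: list of per-site GT character vectors (same length = n samples)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_along(gts), function(i) {
    site <- attr(gts, "sites")[[i]]
    paste(c(site$chrom, site$pos, site$id, site$ref, site$alt, ".", "PASS",
            ".", "GT", gts[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
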