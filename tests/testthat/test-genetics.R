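# Genotype IO, Hardy-Weinberg exact test, SNP QC, genetic-model codings,
# the logistic min-P scan, and genome-wide diagnostics.

test_that("VCF genotypes are read with minor-allele orientation", {
  ids <- c("S1", "S2", "S3", "S4", "S5")
  gts <- list(
    c("0/0", "0/1", "1/1", "0|1", "./."),   # ALT freq 0.5 -> keep ALT
    c("1/1", "1/1", "0/1", "1/1", "1/1"),   # ALT freq 0.9 -> dosage counts REF
    c("0/0", "0/0", "0/1", "0/0", "0/0")
  )
  attr(gts, "sites") <- list(
    list(chrom = 1, pos = 100, id = "rsA", ref = "A", alt = "G"),
    list(chrom = 2, pos = 200, id = "rsB", ref = "T", alt = "C"),
    list(chrom = 3, pos = 300, id = "rsC", ref = "A", alt = "C")
  )
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, ids, gts)
  g <- read_genotypes(f)
  expect_equal(unname(g$dosage[, "rsA"]), c(0, 1, 2, 1, NA))
  # heterozygote is 1 regardless of phase; site rsB flips to REF counts
  expect_equal(unname(g$dosage[, "rsB"]), c(0, 0, 1, 0, 0))
  expect_true(g$info$minor_is_ref[g$info$snp_id == "rsB"])
  expect_equal(unname(g$dosage[, "rsC"]), c(0, 0, 1, 0, 0))
})

test_that("multi-allelic VCF sites are skipped with a warning", {
  ids <- c("S1", "S2")
  gts <- list(c("0/1", "1/2"), c("0/0", "0/1"))
  attr(gts, "sites") <- list(
    list(chrom = 1, pos = 1, id = "multi", ref = "A", alt = "G,T"),
    list(chrom = 1, pos = 2, id = "bi", ref = "A", alt = "G")
  )
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, ids, gts)
  expect_warning(g <- read_genotypes(f), "multi-allelic")
  expect_equal(colnames(g$dosage), "bi")
})

test_that("HWE exact test: monomorphic, worked example, exhaustive small-n oracle", {
  expect_equal(hwe_exact_test(57, 0, 0), 1)
  expect_equal(hwe_exact_test(57, 14, 50), oracle_hwe(57, 14, 50),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), class = "mrsurv_domain_error")
  expect_error(hwe_exact_test(-1, 2, 0), class = "mrsurv_domain_error")

  # random sweep here; the exhaustive total <= 50 sweep runs in the
  # acceptance suite
  set.seed(5)
  for (r in 1:200) {
    n <- sample(1:40, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1); c <- n - a - b
    expect_equal(hwe_exact_test(a, b, c), oracle_hwe(a, b, c),
                 tolerance = 1e-12,
                 label = sprintf("counts (%d,%d,%d)", a, b, c))
  }
})

test_that("SNP QC applies boundary-inclusive pass rules with reasons", {
  set.seed(8)
  n <- 200
  # engineered: s_cr fails call rate, s_maf fails MAF, s_hwe fails HWE
  good <- rbinom(n, 2, 0.3)
  s_cr <- good; s_cr[1:11] <- NA                  # call rate 94.5%
  s_maf <- rbinom(n, 2, 0.02)
  s_hwe <- c(rep(1, 150), rep(0, 25), rep(2, 25)) # het excess
  m <- cbind(good = good, s_cr = s_cr, s_maf = s_maf, s_hwe = s_hwe)
  qc <- snp_qc(genotype_matrix(m))
  expect_equal(qc$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(qc$reasons[2], "call_rate")
  expect_equal(qc$reasons[3], "maf")
  expect_equal(qc$reasons[4], "hwe")

  # boundaries pass: call rate exactly 0.95, MAF exactly 0.05
  s_cr95 <- good; s_cr95[1:10] <- NA              # exactly 95%
  maf05 <- c(rep(1, 20), rep(0, 180))             # freq 0.05, hwe-fine
  qc2 <- snp_qc(genotype_matrix(cbind(a = s_cr95, b = maf05)))
  expect_equal(qc2$call_rate[1], 0.95)
  expect_true(qc2$pass[1])
  expect_equal(qc2$maf[2], 0.05)
  expect_true(qc2$pass[2])
})

test_that("genetic-model encodings and min-P bookkeeping", {
  expect_equal(encode_genetic_model(c(0, 1, 2), "additive"), c(0, 1, 2))
  expect_equal(encode_genetic_model(c(0, 1, 2), "dominant"), c(0, 1, 1))
  expect_equal(encode_genetic_model(c(0, 1, 2), "recessive"), c(0, 0, 1))
  expect_equal(encode_genetic_model(c(1, NA), "dominant"), c(1, NA))
  expect_error(encode_genetic_model(c(0, 1), "codominant"),
               class = "mrsurv_parameter_error")
})

test_that("association scan matches a brute-force likelihood maximization", {
  set.seed(12)
  n <- 200
  g <- rbinom(n, 2, 0.35)
  age <- rnorm(n, 50, 8); male <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.8 + 0.5 * (g >= 1) + 0.02 * (age - 50)))
  gt <- genotype_matrix(matrix(g, ncol = 1, dimnames = list(NULL, "snp")))
  sc <- logistic_association_scan(gt, y, data.frame(age = age, male = male))

  X0 <- cbind(1, age, male)
  for (m in c("additive", "dominant", "recessive")) {
    X <- cbind(X0, encode_genetic_model(g, m))
    op <- optim(rep(0, 4), oracle_logistic_nll, gr = oracle_logistic_grad,
                X = X, y = y, method = "BFGS",
                control = list(maxit = 1000, reltol = 1e-15))
    expect_lt(abs(sc[[paste0("beta_", m)]] - op$par[4]), 1e-6, label = m)
  }
  expect_equal(sc$min_p,
               min(sc$p_additive, sc$p_dominant, sc$p_recessive))
  expect_equal(sc[[paste0("p_", sc$best_model)]], sc$min_p)
})

test_that("scan symmetry: balanced dosage distribution gives beta 0", {
  g <- rep(c(0, 1, 2), each = 20)
  y <- rep(rep(c(0, 1), each = 10), 3)  # identical distribution per dosage
  gt <- genotype_matrix(matrix(g, ncol = 1, dimnames = list(NULL, "s")))
  sc <- logistic_association_scan(gt, y, covariates = NULL)
  expect_equal(sc$beta_additive, 0, tolerance = 1e-8)
  expect_equal(sc$p_additive, 1, tolerance = 1e-6)
})

test_that("monomorphic and separated models are flagged, not mis-reported", {
  set.seed(3)
  n <- 80
  g_mono <- c(rbinom(n - 1, 1, 0.4), 0)          # no homozygote minor
  y <- rbinom(n, 1, 0.4)
  gt <- genotype_matrix(matrix(g_mono, ncol = 1, dimnames = list(NULL, "s")))
  sc <- logistic_association_scan(gt, y)
  expect_true(is.na(sc$p_recessive))              # recessive monomorphic
  expect_false(is.na(sc$p_additive))

  g_sep <- c(rep(0, 40), rep(2, 40))
  y_sep <- c(rep(0, 40), rep(1, 40))              # perfect separation
  gt2 <- genotype_matrix(matrix(g_sep, ncol = 1, dimnames = list(NULL, "s")))
  sc2 <- logistic_association_scan(gt2, y_sep)
  expect_true(is.na(sc2$p_additive))
})

test_that("genomic inflation factor definition and null behaviour", {
  expect_equal(genomic_inflation_factor(chi2 = rep(0.4549364, 5)), 1,
               tolerance = 1e-6)
  expect_equal(genomic_inflation_factor(chi2 = c(1, 2, 3)), 2 / 0.4549364,
               tolerance = 1e-4)
  set.seed(99)
  lam <- genomic_inflation_factor(p = runif(50000))
  expect_gt(lam, 0.97); expect_lt(lam, 1.03)
  expect_error(genomic_inflation_factor(chi2 = numeric(0)),
               class = "mrsurv_domain_error")
})

test_that("QQ/Manhattan tables follow the stated conventions", {
  res <- data.frame(snp_id = c("a", "b", "c"), chrom = 1:3, pos = 1:3,
                    min_p = c(0.5, 0.01, 0.2))
  tabs <- qq_manhattan_tables(res)
  n <- 3
  expect_equal(tabs$qq$expected, -log10((1:3 - 0.5) / n))
  expect_equal(tabs$qq$observed[1], 2)  # p = 0.01 -> -log10 = 2
  expect_equal(tabs$manhattan$neg_log10_p, -log10(res$min_p))

  one <- qq_manhattan_tables(data.frame(snp_id = "x", min_p = 0.01))
  expect_equal(one$qq$observed, 2)
})

test_that("null-panel QQ points stay inside beta order-statistic bands", {
  qc <- quick_cohort(n = 500, seed = 77, n_null_snps = 150,
                     geno_missing_rate = 0)
  part <- qc$participants
  gen <- qc$gen$genotypes
  nulls <- gen$info$snp_id[gen$info$type == "null"]
  gt <- genotype_matrix(gen$dosage[, nulls], gen$info[match(nulls, gen$info$snp_id), ])
  sc <- logistic_association_scan(gt, part$hypoalbuminemia,
                                  part[, c("age", "male")])
  p <- sort(sc$p_additive[!is.na(sc$p_additive)])
  m <- length(p)
  lo <- qbeta(0.025, seq_len(m), m - seq_len(m) + 1)
  hi <- qbeta(0.975, seq_len(m), m - seq_len(m) + 1)
  expect_gte(mean(p >= lo & p <= hi), 0.93)
})
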