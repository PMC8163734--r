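# Cohort derivation: parsing contracts, eligibility filtering, outcome
# detection, BP change rates, CKD-EPI eGFR, and the descriptive table.

make_pheno_file <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

base_pheno <- function() {
  data.frame(
    subject_id = rep(c("A", "B"), each = 2),
    visit_month = rep(c(0, 24), 2),
    sbp = c(120, 125, 118, 142),
    dbp = c(78, 80, 74, 92),
    med_flag = 0L,
    albumin = rep(c(4.2, 3.8), each = 2),
    age = rep(c(50, 61), each = 2),
    sex = rep(c("M", "F"), each = 2),
    smoker = rep(c(1L, 0L), each = 2),
    stringsAsFactors = FALSE
  )
}

test_that("phenotype parser enforces its error contracts", {
  df <- base_pheno()
  ph <- read_phenotype_table(make_pheno_file(df))
  expect_s3_class(ph, "cohort")
  expect_equal(nrow(ph$participants), 2)

  dup <- rbind(df, df[1, ])
  expect_error(read_phenotype_table(make_pheno_file(dup)),
               class = "mrsurv_parse_error")

  bad <- df
  bad$sbp <- as.character(bad$sbp)
  bad$sbp[3] <- "abc"
  err <- tryCatch(read_phenotype_table(make_pheno_file(bad)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "row 3")
  expect_match(err, "sbp")

  noalb <- df[, setdiff(names(df), "albumin")]
  expect_error(read_phenotype_table(make_pheno_file(noalb)),
               class = "mrsurv_parse_error")

  # schema mapping renames a column into place
  ren <- df
  names(ren)[names(ren) == "sbp"] <- "SBP_mmHg"
  ph2 <- read_phenotype_table(make_pheno_file(ren),
                              schema = list(sbp = "SBP_mmHg"))
  expect_equal(ph2$visits$sbp, df$sbp)
})

test_that("hypoalbuminemia classification has an inclusive 4.0 boundary", {
  expect_true(classify_hypoalbuminemia(3.9))
  expect_true(classify_hypoalbuminemia(4.0))
  expect_false(classify_hypoalbuminemia(4.01))
  expect_error(classify_hypoalbuminemia(0), class = "mrsurv_domain_error")
  expect_identical(classify_hypoalbuminemia(NA_real_), NA)
})

test_that("hypertension detection fires on BP threshold or medication", {
  v <- data.frame(visit_month = c(0, 24, 48), sbp = c(120, 138, 142),
                  dbp = c(80, 88, 80), med_flag = c(0, 0, 0))
  d <- detect_hypertension(v)
  expect_true(d$event)
  expect_equal(d$month, 48)

  vmed <- data.frame(visit_month = c(0, 24), sbp = c(118, 120),
                     dbp = c(70, 76), med_flag = c(0, 1))
  dmed <- detect_hypertension(vmed)
  expect_true(dmed$event)
  expect_equal(dmed$month, 24)

  vno <- data.frame(visit_month = c(0, 24, 48), sbp = c(120, 139, 139),
                    dbp = c(80, 89, 89), med_flag = 0)
  dno <- detect_hypertension(vno)
  expect_false(dno$event)
  expect_equal(dno$month, 48)

  expect_warning(d0 <- detect_hypertension(vno[1, ]), "follow-up")
  expect_equal(d0$month, 0)
})

test_that("earlier medication never delays the detected event (monotonicity)", {
  set.seed(4)
  for (r in 1:20) {
    k <- 5
    v <- data.frame(visit_month = seq(0, 96, by = 24),
                    sbp = runif(k, 110, 150), dbp = runif(k, 70, 95),
                    med_flag = rbinom(k, 1, 0.3))
    m1 <- detect_hypertension(v)
    v2 <- v
    j <- sample(2:k, 1)
    v2$med_flag[j] <- 1
    m2 <- detect_hypertension(v2)
    expect_lte(m2$month, m1$month)
  }
})

test_that("BP change rate follows the last-minus-baseline convention", {
  v <- data.frame(visit_month = c(0, 24, 48), sbp = c(110, 118, 122),
                  dbp = c(70, 71, 76), med_flag = 0)
  d <- compute_delta_bp(v)
  expect_equal(d$delta_sbp, (122 - 110) / 48)
  expect_equal(d$delta_dbp, (76 - 70) / 48)

  same <- data.frame(visit_month = c(0, 24), sbp = c(120, 120),
                     dbp = c(80, 80), med_flag = 0)
  expect_equal(compute_delta_bp(same)$delta_sbp, 0)

  down <- data.frame(visit_month = c(0, 24), sbp = c(120, 114),
                     dbp = c(80, 78), med_flag = 0)
  expect_equal(compute_delta_bp(down)$delta_sbp, -0.25)

  # diagnosis visit excluded by default, included on request
  ev <- data.frame(visit_month = c(0, 24, 48), sbp = c(110, 120, 145),
                   dbp = c(70, 75, 92), med_flag = 0)
  expect_equal(compute_delta_bp(ev, event_month = 48)$delta_sbp, (120 - 110) / 24)
  expect_equal(compute_delta_bp(ev, event_month = 48,
                                include_diagnosis_visit = TRUE)$delta_sbp,
               (145 - 110) / 48)

  # single usable visit -> undefined
  expect_false(compute_delta_bp(ev[1, ])$defined)
})

test_that("BP change of an exactly linear trajectory equals its slope", {
  slope_s <- 0.21; slope_d <- -0.07
  v <- data.frame(visit_month = seq(0, 120, by = 24))
  v$sbp <- 115 + slope_s * v$visit_month
  v$dbp <- 76 + slope_d * v$visit_month
  v$med_flag <- 0
  d <- compute_delta_bp(v)
  expect_equal(d$delta_sbp, slope_s, tolerance = 1e-12)
  expect_equal(d$delta_dbp, slope_d, tolerance = 1e-12)
})

test_that("CKD-EPI eGFR matches independent evaluations and is monotone", {
  # 144 * (0.7/0.7)^-0.329 * 0.993^50 evaluated independently
  expect_equal(compute_ckd_epi_egfr(0.7, 50, "F"), 144 * 0.993^50,
               tolerance = 1e-10)
  expect_equal(round(compute_ckd_epi_egfr(0.7, 50, "F"), 1), 101.4)
  expect_equal(compute_ckd_epi_egfr(1.2, 60, "M"),
               141 * (1.2 / 0.9)^(-1.209) * 0.993^60, tolerance = 1e-10)
  expect_equal(round(compute_ckd_epi_egfr(1.2, 60, "M"), 1), 65.3)
  expect_equal(compute_ckd_epi_egfr(0.9, 0, "M"), 141)
  expect_error(compute_ckd_epi_egfr(0, 50, "M"), class = "mrsurv_domain_error")

  set.seed(2)
  for (sx in c("M", "F")) {
    cr <- sort(runif(20, 0.4, 3))
    expect_true(all(diff(compute_ckd_epi_egfr(cr, 50, sx)) < 0))
    ages <- sort(runif(20, 20, 90))
    expect_true(all(diff(compute_ckd_epi_egfr(1.0, ages, sx)) < 0))
  }
})

test_that("eligibility filter counts, first-match reasons, idempotence", {
  part <- data.frame(
    subject_id = sprintf("P%02d", 1:10),
    albumin = c(NA, rep(4.2, 9)),
    age = 50, sex = "M", smoker = 0L,
    flag_htn = c(0, 1, 1, rep(0, 7)),
    flag_dm = c(0, 0, 0, 1, rep(0, 6)),
    flag_ckd = c(0, 0, 0, 1, rep(0, 6)),  # subject 4 has both dm and ckd
    flag_cvd = 0L, flag_cancer = 0L,
    stringsAsFactors = FALSE
  )
  coh <- list(participants = part,
              visits = data.frame(subject_id = part$subject_id, visit_month = 0,
                                  sbp = 120, dbp = 80, med_flag = 0L))
  res <- apply_eligibility_filter(coh)
  expect_equal(nrow(res$cohort$participants), 6)
  expect_equal(nrow(res$log), 4)
  expect_equal(res$log$reason[res$log$subject_id == "P01"], "missing_data")
  expect_equal(res$log$reason[res$log$subject_id == "P04"], "diabetes")

  # idempotent; clean input passes through unchanged
  res2 <- apply_eligibility_filter(res$cohort)
  expect_equal(res2$cohort$participants, res$cohort$participants)
  expect_equal(nrow(res2$log), 0)
})

test_that("vectorized cohort derivation agrees with the per-subject operations", {
  qc <- quick_cohort(n = 250, seed = 31)
  part <- qc$participants
  v <- qc$cohort$visits
  for (sid in sample(part$subject_id, 25)) {
    vi <- v[v$subject_id == sid, ]
    det <- detect_hypertension(vi)
    i <- match(sid, part$subject_id)
    expect_equal(part$event[i], det$event, label = sid)
    expect_equal(part$time_month[i], det$month, label = sid)
    del <- compute_delta_bp(vi, event_month = if (det$event) det$month else NA)
    expect_equal(part$delta_sbp[i], del$delta_sbp, label = sid)
    expect_equal(part$delta_dbp[i], del$delta_dbp, label = sid)
  }
})

test_that("baseline table reproduces enumerable small-sample tests", {
  part <- data.frame(
    subject_id = as.character(1:6),
    grp = rep(c(FALSE, TRUE), each = 3),
    val = c(1, 2, 3, 4, 5, 6),
    cat = c("a", "a", "a", "b", "b", "b"),
    stringsAsFactors = FALSE
  )
  coh <- list(participants = part)
  tab <- summarize_baseline(coh, group = "grp", vars = c("val", "cat"))
  # Mann-Whitney {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 0.1
  expect_equal(tab$p[tab$variable == "val"], 0.1, tolerance = 1e-12)
  # Fisher exact on ((3,0),(0,3)): p = 0.1
  expect_equal(tab$p[tab$variable == "cat"], 0.1, tolerance = 1e-12)

  # identical groups -> chi-square statistic 0 (p = 1)
  part2 <- data.frame(subject_id = as.character(1:40),
                      grp = rep(c(FALSE, TRUE), each = 20),
                      cat = rep(rep(c("x", "y"), each = 10), 2),
                      stringsAsFactors = FALSE)
  tab2 <- summarize_baseline(list(participants = part2), group = "grp",
                             vars = "cat")
  expect_equal(tab2$p, 1)
  expect_equal(tab2$test, "chi-square")

  # constant variable -> NA p
  part2$const <- 1.5
  tab3 <- summarize_baseline(list(participants = part2), group = "grp",
                             vars = "const")
  expect_true(is.na(tab3$p))
})
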