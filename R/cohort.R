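# Phenotype-table reading, eligibility filtering, and derived variables:
# incident-hypertension detection on the visit grid, BP change rates,
# CKD-EPI eGFR, hypoalbuminemia status, and descriptive statistics.

PHENO_NUMERIC <- c("visit_month", "sbp", "dbp", "med_flag", "albumin", "age",
                   "smoker", "bmi", "waist", "hemoglobin", "platelet", "hba1c",
                   "alt", "ggt", "tg", "hdl", "creatinine", "flag_htn",
                   "flag_dm", "flag_ckd", "flag_cvd", "flag_cancer")

VISIT_COLS <- c("subject_id", "visit_month", "sbp", "dbp", "med_flag")

#' Read a long phenotype/visit table
#'
#' Expects a delimited long table with one row per subject-visit carrying
#' the visit measurements (`visit_month`, `sbp`, `dbp`, `med_flag`) and the
#' subject-level baseline columns (`albumin`, `age`, `sex`, `smoker`,
#' optional labs and exclusion flags) repeated on each row. Missing values
#' are preserved as missing, never imputed. Non-numeric entries in numeric
#' columns raise a parse error naming the row and column; duplicated
#' (subject, visit) pairs are an error.
#'
#' @param path File path (TSV, or `sep` override).
#' @param schema Optional named list mapping canonical column names to the
#'   file's column names, e.g. `list(sbp = "SBP_mmHg")`.
#' @param sep Field separator (default tab).
#' @return List of class `cohort` with `participants` (one row per subject)
#'   and `visits` (subject_id, visit_month, sbp, dbp, med_flag).
#' @export
read_phenotype_table <- function(path, schema = NULL, sep = "\t") {
  if (!file.exists(path)) {
    stop_mrsurv("file not found: %s", path, class = "mrsurv_io_error")
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      j <- match(schema[[canon]], names(raw))
      if (is.na(j)) {
        stop_mrsurv("schema maps '%s' to unknown column '%s'", canon,
                    schema[[canon]], class = "mrsurv_parse_error")
      }
      names(raw)[j] <- canon
    }
  }
  need <- c("subject_id", "visit_month", "sbp", "dbp", "med_flag",
            "albumin", "age", "sex")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop_mrsurv("missing required column(s): %s", paste(miss, collapse = ", "),
                class = "mrsurv_parse_error")
  }
  for (cl in intersect(PHENO_NUMERIC, names(raw))) {
    v <- raw[[cl]]
    conv <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(conv) & !(is.na(v) | v %in% c("", "NA")))
    if (length(bad) > 0) {
      stop_mrsurv("non-numeric value '%s' in column '%s' at row %d",
                  v[bad[1]], cl, bad[1], class = "mrsurv_parse_error")
    }
    raw[[cl]] <- conv
  }
  if (anyDuplicated(raw[, c("subject_id", "visit_month")])) {
    dup <- raw$subject_id[duplicated(raw[, c("subject_id", "visit_month")])][1]
    stop_mrsurv("duplicated subject/visit rows (subject '%s')", dup,
                class = "mrsurv_parse_error")
  }
  bp_bad <- with(raw, (!is.na(sbp) & (sbp <= 50 | sbp >= 300)))
  if (any(bp_bad)) {
    stop_mrsurv("BP outside plausible range (50, 300) at row %d",
                which(bp_bad)[1], class = "mrsurv_parse_error")
  }
  raw <- raw[order(raw$subject_id, raw$visit_month), ]
  rownames(raw) <- NULL
  visits <- raw[, VISIT_COLS]
  part <- raw[!duplicated(raw$subject_id),
              setdiff(names(raw), c("visit_month", "sbp", "dbp", "med_flag")),
              drop = FALSE]
  rownames(part) <- NULL
  structure(list(participants = part, visits = visits), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects, %d visit rows\n",
              nrow(x$participants), nrow(x$visits)))
  invisible(x)
}

#' Classify hypoalbuminemia
#'
#' Serum albumin at or below 4.0 g/dL (boundary inclusive).
#'
#' @param albumin Albumin, g/dL (> 0; NA allowed and propagates).
#' @param cutoff Cutoff, g/dL (default 4.0).
#' @return Logical vector.
#' @export
#' @examples
#' classify_hypoalbuminemia(c(3.9, 4.0, 4.01))
classify_hypoalbuminemia <- function(albumin, cutoff = 4.0) {
  if (any(albumin <= 0, na.rm = TRUE)) {
    stop_mrsurv("albumin must be positive", class = "mrsurv_domain_error")
  }
  albumin <= cutoff
}

#' Detect incident hypertension from a subject's visit records
#'
#' Event at the first post-baseline visit with SBP >= 140 mmHg, DBP >= 90
#' mmHg, or antihypertensive medication use; otherwise censored at the last
#' visit. Thresholds are inclusive and configurable.
#'
#' @param visits Data frame for one subject with `visit_month`, `sbp`,
#'   `dbp`, `med_flag`.
#' @param sbp_threshold,dbp_threshold Diagnostic thresholds, mmHg.
#' @return List with `event` (logical) and `month` (event or censor month).
#' @export
detect_hypertension <- function(visits, sbp_threshold = 140, dbp_threshold = 90) {
  fu <- visits[visits$visit_month > 0, , drop = FALSE]
  if (nrow(fu) == 0) {
    warning("no follow-up visits; censoring at month 0")
    return(list(event = FALSE, month = 0))
  }
  fu <- fu[order(fu$visit_month), , drop = FALSE]
  hit <- (!is.na(fu$sbp) & fu$sbp >= sbp_threshold) |
    (!is.na(fu$dbp) & fu$dbp >= dbp_threshold) |
    (!is.na(fu$med_flag) & fu$med_flag > 0)
  if (any(hit)) {
    list(event = TRUE, month = fu$visit_month[which(hit)[1]])
  } else {
    list(event = FALSE, month = max(fu$visit_month))
  }
}

#' Average rate of blood-pressure change
#'
#' (Last pre-diagnosis BP - baseline BP) / months elapsed, in mmHg/month;
#' positive values mean rising BP. For censored subjects the last available
#' visit is used. By default the diagnosis visit itself is excluded.
#'
#' @param visits One subject's visit data frame.
#' @param event_month Detection month for events, `NA`/`Inf` if censored.
#' @param include_diagnosis_visit If `TRUE`, the detection visit itself may
#'   serve as the last measurement.
#' @return List with `delta_sbp`, `delta_dbp` (NA when fewer than two
#'   usable visits) and `defined`.
#' @export
#' @examples
#' v <- data.frame(visit_month = c(0, 48), sbp = c(110, 122), dbp = c(70, 76))
#' compute_delta_bp(v)$delta_sbp  # 0.25
compute_delta_bp <- function(visits, event_month = NA,
                             include_diagnosis_visit = FALSE) {
  v <- visits[order(visits$visit_month), , drop = FALSE]
  cut <- if (is.na(event_month) || !is.finite(event_month)) Inf
         else if (include_diagnosis_visit) event_month + 1e-9
         else event_month
  v <- v[v$visit_month < cut & !is.na(v$sbp) & !is.na(v$dbp), , drop = FALSE]
  base <- v[v$visit_month == 0, , drop = FALSE]
  if (nrow(v) < 2 || nrow(base) == 0) {
    return(list(delta_sbp = NA_real_, delta_dbp = NA_real_, defined = FALSE))
  }
  last <- v[nrow(v), ]
  mo <- last$visit_month - 0
  list(delta_sbp = (last$sbp - base$sbp[1]) / mo,
       delta_dbp = (last$dbp - base$dbp[1]) / mo,
       defined = TRUE)
}

#' CKD-EPI (2009) estimated glomerular filtration rate
#'
#' Creatinine-based CKD-EPI equation without the race coefficient (a
#' single-ethnicity East-Asian cohort is the intended use; noted in output
#' metadata). Vectorized.
#'
#' @param creatinine Serum creatinine, mg/dL (> 0).
#' @param age Age in years (> 0).
#' @param sex `"M"`/`"F"` (or `"male"`/`"female"`).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
#' @examples
#' compute_ckd_epi_egfr(0.7, 50, "F")  # ~101.4
compute_ckd_epi_egfr <- function(creatinine, age, sex) {
  if (any(creatinine <= 0, na.rm = TRUE) || any(age < 0, na.rm = TRUE)) {
    stop_mrsurv("creatinine and age must be positive", class = "mrsurv_domain_error")
  }
  female <- toupper(substr(as.character(sex), 1, 1)) == "F"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  const <- ifelse(female, 144, 141)  # published sex-specific constants
  scr_k <- creatinine / kappa
  const * pmin(scr_k, 1)^alpha * pmax(scr_k, 1)^(-1.209) * 0.993^age
}

#' Derive the analysis cohort from a parsed phenotype table
#'
#' Vectorized over subjects: detects incident hypertension on the visit
#' grid (agreeing with [detect_hypertension()] per subject), computes BP
#' change rates, eGFR, and hypoalbuminemia status, and attaches baseline
#' BP. Subjects keep missing values; eligibility filtering is separate.
#'
#' @param cohort A `cohort` from [read_phenotype_table()] (or an equivalent
#'   list with `participants` and `visits`).
#' @param sbp_threshold,dbp_threshold Hypertension thresholds, mmHg.
#' @param hypoalbuminemia_cutoff Albumin cutoff, g/dL.
#' @param include_diagnosis_visit Passed to the BP-change rule.
#' @return The `cohort` with derived columns added to `participants`:
#'   `event`, `time_month`, `baseline_sbp`, `baseline_dbp`, `delta_sbp`,
#'   `delta_dbp`, `egfr`, `hypoalbuminemia`, `male`.
#' @export
derive_cohort <- function(cohort, sbp_threshold = 140, dbp_threshold = 90,
                          hypoalbuminemia_cutoff = 4.0,
                          include_diagnosis_visit = FALSE) {
  part <- cohort$participants
  v <- cohort$visits
  v <- v[order(v$subject_id, v$visit_month), ]
  f <- factor(v$subject_id, levels = part$subject_id)
  mo <- v$visit_month
  hit <- ((!is.na(v$sbp) & v$sbp >= sbp_threshold) |
            (!is.na(v$dbp) & v$dbp >= dbp_threshold) |
            (!is.na(v$med_flag) & v$med_flag > 0)) & mo > 0
  ev_month <- tapply(ifelse(hit, mo, Inf), f, min)
  fu_last <- suppressWarnings(tapply(ifelse(mo > 0, mo, -Inf), f, max))
  event <- is.finite(ev_month)
  time_m <- ifelse(event, ev_month, pmax(fu_last, 0))

  b0 <- mo == 0
  idx0 <- tapply(ifelse(b0, seq_along(mo), NA_integer_), f, function(i) i[!is.na(i)][1])
  baseline_sbp <- v$sbp[idx0]
  baseline_dbp <- v$dbp[idx0]

  cut <- ifelse(event, ev_month, Inf)[as.integer(f)]
  if (include_diagnosis_visit) cut <- cut + 1e-9
  elig <- mo < cut & !is.na(v$sbp) & !is.na(v$dbp)
  idxl <- suppressWarnings(tapply(ifelse(elig, seq_along(mo), -Inf), f, max))
  idxl[!is.finite(idxl)] <- NA
  last_mo <- mo[idxl]
  ok <- !is.na(idxl) & !is.na(last_mo) & last_mo > 0 &
    !is.na(baseline_sbp) & !is.na(baseline_dbp)
  delta_sbp <- delta_dbp <- rep(NA_real_, nrow(part))
  delta_sbp[ok] <- (v$sbp[idxl[ok]] - baseline_sbp[ok]) / last_mo[ok]
  delta_dbp[ok] <- (v$dbp[idxl[ok]] - baseline_dbp[ok]) / last_mo[ok]

  part$event <- as.logical(event)
  part$time_month <- as.numeric(time_m)
  part$baseline_sbp <- baseline_sbp
  part$baseline_dbp <- baseline_dbp
  part$delta_sbp <- delta_sbp
  part$delta_dbp <- delta_dbp
  part$hypoalbuminemia <- classify_hypoalbuminemia(part$albumin,
                                                   hypoalbuminemia_cutoff)
  if (all(c("creatinine", "age", "sex") %in% names(part))) {
    part$egfr <- compute_ckd_epi_egfr(part$creatinine, part$age, part$sex)
  }
  part$male <- as.integer(toupper(substr(as.character(part$sex), 1, 1)) == "M")
  cohort$participants <- part
  cohort$derived <- TRUE
  cohort$meta <- list(sbp_threshold = sbp_threshold,
                      dbp_threshold = dbp_threshold,
                      hypoalbuminemia_cutoff = hypoalbuminemia_cutoff,
                      egfr = "CKD-EPI 2009, no race coefficient",
                      time_unit = "months")
  cohort
}

#' Apply the baseline eligibility filter
#'
#' Removes subjects with missing analysis variables or any prevalent
#' baseline condition, logging exactly one reason per excluded subject —
#' the first matching in the order: missing data, prevalent hypertension,
#' diabetes mellitus, chronic kidney disease, cardiovascular disease,
#' malignancy. Idempotent.
#'
#' @param cohort A derived `cohort` (participants carry `flag_*` columns).
#' @param required_vars Columns that must be non-missing to be retained.
#' @return List with `cohort` (filtered) and `log` (subject_id, reason).
#' @export
apply_eligibility_filter <- function(cohort,
                                     required_vars = c("albumin", "age", "sex", "smoker")) {
  part <- cohort$participants
  flags <- c(prevalent_hypertension = "flag_htn", diabetes = "flag_dm",
             chronic_kidney_disease = "flag_ckd",
             cardiovascular_disease = "flag_cvd", malignancy = "flag_cancer")
  miss_flag <- setdiff(unname(flags), names(part))
  if (length(miss_flag) > 0) {
    stop_mrsurv("exclusion flag column(s) absent: %s",
                paste(miss_flag, collapse = ", "), class = "mrsurv_parameter_error")
  }
  req <- intersect(required_vars, names(part))
  reason <- rep(NA_character_, nrow(part))
  if (length(req) > 0) {
    incomplete <- !stats::complete.cases(part[, req, drop = FALSE])
    reason[incomplete] <- "missing_data"
  }
  for (rn in names(flags)) {
    fl <- part[[flags[[rn]]]]
    take <- is.na(reason) & !is.na(fl) & fl > 0
    reason[take] <- rn
  }
  keep <- is.na(reason)
  if (!any(keep)) warning("eligibility filter removed every subject")
  log <- data.frame(subject_id = part$subject_id[!keep],
                    reason = reason[!keep], stringsAsFactors = FALSE)
  out <- cohort
  out$participants <- part[keep, , drop = FALSE]
  rownames(out$participants) <- NULL
  out$visits <- cohort$visits[cohort$visits$subject_id %in% out$participants$subject_id, ,
                              drop = FALSE]
  list(cohort = out, log = log)
}

# Mean (SD) / n (%) descriptive comparison of two groups.
#' Baseline descriptive table by group
#'
#' For each variable: mean +/- SD (quantitative) or count (%) (binary /
#' categorical) per group, with a two-group p-value. A Kolmogorov-Smirnov
#' normality check decides whether a logarithmic transform is applied
#' before testing positive-valued skewed variables; quantitative variables
#' are compared with the Mann-Whitney U test, categorical ones with the
#' chi-square test, or Fisher's exact test when any expected cell count is
#' below 5. Constant variables report `NA`.
#'
#' @param cohort A derived `cohort`.
#' @param group Name of a logical/binary grouping column (default
#'   `hypoalbuminemia`).
#' @param vars Variables to summarize (default: sensible baseline set).
#' @return Data frame with one row per variable.
#' @export
summarize_baseline <- function(cohort, group = "hypoalbuminemia", vars = NULL) {
  part <- cohort$participants
  g <- part[[group]]
  if (is.null(g) || length(unique(stats::na.omit(as.integer(g)))) != 2) {
    stop_mrsurv("grouping variable must be binary", class = "mrsurv_parameter_error")
  }
  g <- as.logical(g)
  if (is.null(vars)) {
    cand <- c("age", "sex", "smoker", "bmi", "waist", "baseline_sbp",
              "baseline_dbp", "hemoglobin", "platelet", "albumin", "hba1c",
              "egfr", "alt", "ggt", "tg", "hdl", "creatinine")
    vars <- intersect(cand, names(part))
  }
  rows <- lapply(vars, function(vn) {
    x <- part[[vn]]
    categ <- is.character(x) || is.factor(x) || is.logical(x) ||
      (is.numeric(x) && length(unique(stats::na.omit(x))) <= 2)
    if (!categ) {
      x0 <- x[!g & !is.na(x)]; x1 <- x[g & !is.na(x)]
      s0 <- sprintf("%.2f ± %.2f", mean(x0), stats::sd(x0))
      s1 <- sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1))
      if (stats::sd(c(x0, x1)) == 0) {
        return(data.frame(variable = vn, group0 = s0, group1 = s1,
                          test = "none", transform = "none", p = NA_real_))
      }
      pooled <- c(x0, x1)
      ksp <- tryCatch(suppressWarnings(
        stats::ks.test(pooled, "pnorm", mean(pooled), stats::sd(pooled))$p.value),
        error = function(e) NA_real_)
      transform <- "none"
      if (!is.na(ksp) && ksp < 0.05 && all(pooled > 0)) {
        x0 <- log(x0); x1 <- log(x1); transform <- "log"
      }
      p <- tryCatch(suppressWarnings(stats::wilcox.test(x0, x1)$p.value),
                    error = function(e) NA_real_)
      data.frame(variable = vn, group0 = s0, group1 = s1,
                 test = "mann-whitney", transform = transform, p = p)
    } else {
      xx <- as.character(x)
      tab <- table(xx, g)
      n0 <- sum(!g & !is.na(x)); n1 <- sum(g & !is.na(x))
      lev <- rownames(tab)[nrow(tab)]
      s0 <- sprintf("%d (%.1f%%)", tab[lev, "FALSE"], 100 * tab[lev, "FALSE"] / n0)
      s1 <- sprintf("%d (%.1f%%)", tab[lev, "TRUE"], 100 * tab[lev, "TRUE"] / n1)
      if (nrow(tab) < 2) {
        return(data.frame(variable = vn, group0 = s0, group1 = s1,
                          test = "none", transform = "none", p = NA_real_))
      }
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
        test <- "chi-square"
      }
      data.frame(variable = vn, group0 = s0, group1 = s1,
                 test = test, transform = "none", p = p)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "group_sizes") <- c(`FALSE` = sum(!g, na.rm = TRUE),
                                `TRUE` = sum(g, na.rm = TRUE))
  out
}
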