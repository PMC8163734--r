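# SNP containers, quality control, exact Hardy-Weinberg testing, and the
# three-genetic-model (additive/dominant/recessive) min-P logistic scan.

#' Genotype matrix container
#'
#' Dosages count minor alleles and must lie in `{0, 1, 2, NA}`. Rows are
#' subjects, columns SNPs; `info` carries per-SNP metadata.
#'
#' @param dosage Integer/numeric matrix, subjects x SNPs, values 0/1/2/NA.
#' @param info Optional data frame with one row per SNP (`snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, ...). A minimal one is built if absent.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, info = NULL) {
  dosage <- as.matrix(dosage)
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) {
    stop_mrsurv("dosages must be 0, 1, 2 or NA (%d offending cells)",
                sum(bad), class = "mrsurv_parameter_error")
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("snp_%d", seq_len(ncol(dosage)))
  }
  if (is.null(info)) {
    info <- data.frame(snp_id = colnames(dosage), chrom = NA_integer_,
                       pos = NA_integer_, ref = NA_character_,
                       alt = NA_character_, type = "unknown",
                       stringsAsFactors = FALSE)
  }
  if (nrow(info) != ncol(dosage)) {
    stop_mrsurv("info rows (%d) must match SNP columns (%d)",
                nrow(info), ncol(dosage), class = "mrsurv_shape_error")
  }
  structure(list(dosage = dosage, info = info), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%d instrument, %.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              sum(x$info$type == "instrument"),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(subject_id = rownames(genotypes$dosage),
                   genotypes$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read genotypes from a TSV dosage matrix or a VCF
#'
#' TSV input (`subject_id` column then one column per SNP, cells 0/1/2/NA)
#' is taken at face value: its columns are already dosage-coded and are not
#' reoriented. For VCF input the minor allele is determined from the sample
#' ALT-allele frequency: when the ALT frequency exceeds 0.5 the dosage
#' counts REF alleles instead (ties keep ALT). Heterozygous GT maps to 1
#' regardless of phase; missing GT to NA; multi-allelic sites are skipped
#' with a warning.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_mrsurv("file not found: %s", path, class = "mrsurv_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    df <- read_tsv(path)
    if (names(df)[1] != "subject_id") {
      stop_mrsurv("dosage TSV must start with a 'subject_id' column",
                  class = "mrsurv_parse_error")
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$subject_id
    return(genotype_matrix(m))
  }
  read_genotypes_vcf(path)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_mrsurv("reading VCF requires the 'vcfR' package",
                class = "mrsurv_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic site(s)", sum(multi)))
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
  }
  # allele dosage of ALT: count "1" tokens in GT, any phasing
  alt_count <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }
  dos <- t(apply(gt, 2, alt_count))
  if (nrow(fix) == 1) dos <- matrix(dos, ncol = 1, dimnames = list(colnames(gt), NULL))
  colnames(dos) <- unname(fix[, "ID"])
  flipped <- logical(nrow(fix))
  for (j in seq_len(ncol(dos))) {
    f_alt <- mean(dos[, j], na.rm = TRUE) / 2
    if (is.finite(f_alt) && f_alt > 0.5) {
      dos[, j] <- 2L - dos[, j]
      flipped[j] <- TRUE
    }
  }
  info <- data.frame(
    snp_id = unname(fix[, "ID"]), chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]), ref = unname(fix[, "REF"]),
    alt = unname(fix[, "ALT"]), type = "unknown", minor_is_ref = flipped,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, info)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact p-value: conditional on the observed allele counts, sum
#' the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed table. The conditional
#' distribution is evaluated by the stable recurrence over heterozygote
#' counts of matching parity.
#'
#' @param n_hom_major,n_het,n_hom_minor Genotype counts (non-negative,
#'   total >= 1).
#' @return Exact two-sided p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(57, 14, 50)
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  cnt <- c(n_hom_major, n_het, n_hom_minor)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop_mrsurv("genotype counts must be non-negative integers",
                class = "mrsurv_domain_error")
  }
  n <- sum(cnt)
  if (n < 1) {
    stop_mrsurv("at least one genotype is required", class = "mrsurv_domain_error")
  }
  n_rare <- 2 * n_hom_minor + n_het
  if (n_rare > n) {  # counts given with major/minor swapped; symmetric test
    n_rare <- 2 * n - n_rare
  }
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  probs <- numeric(length(hets))
  # start at the modal-ish midpoint and apply the two-sided recurrence
  mid <- hets[which.min(abs(hets - n_rare * (2 * n - n_rare) / (2 * n)))]
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  if (i_mid < length(hets)) {
    for (i in (i_mid + 1):length(hets)) {
      h <- hets[i - 1]
      r_hom <- (n_rare - h) / 2       # minor homozygotes at h hets
      c_hom <- (2 * n - n_rare - h) / 2
      # P(h+2) / P(h) = 4 * r_hom * c_hom / ((h+2) * (h+1))
      probs[i] <- probs[i - 1] * 4 * r_hom * c_hom / ((h + 2) * (h + 1))
    }
  }
  if (i_mid > 1) {
    for (i in (i_mid - 1):1) {
      h <- hets[i + 1]
      r_hom <- (n_rare - h) / 2
      c_hom <- (2 * n - n_rare - h) / 2
      # P(h-2) / P(h) = h * (h-1) / (4 * (r_hom+1) * (c_hom+1))
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (r_hom + 1) * (c_hom + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(min(n_het, 2 * n - n_het), hets)]
  if (is.na(p_obs)) p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Per-SNP quality control
#'
#' A SNP passes when call rate >= 95%, minor allele frequency >= 0.05 and
#' the Hardy-Weinberg exact p-value >= 0.001 (all boundary-inclusive for
#' passing; thresholds configurable).
#'
#' @param genotypes A [genotype_matrix].
#' @param thresholds Named list with `call_rate`, `maf`, `hwe_p`.
#' @return Data frame with snp_id, call_rate, maf, hwe_p, pass, reasons.
#' @export
snp_qc <- function(genotypes,
                   thresholds = list(call_rate = 0.95, maf = 0.05, hwe_p = 0.001)) {
  dos <- genotypes$dosage
  if (ncol(dos) < 1) {
    stop_mrsurv("at least one SNP required", class = "mrsurv_parameter_error")
  }
  res <- lapply(seq_len(ncol(dos)), function(j) {
    g <- dos[, j]
    cr <- mean(!is.na(g))
    g <- g[!is.na(g)]
    if (length(g) == 0) {
      return(data.frame(snp_id = colnames(dos)[j], call_rate = cr,
                        maf = NA_real_, hwe_p = NA_real_, pass = FALSE,
                        reasons = "call_rate", stringsAsFactors = FALSE))
    }
    f <- mean(g) / 2
    maf <- min(f, 1 - f)
    if (f <= 0.5) {
      hw <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    } else {
      hw <- hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
    }
    fails <- c(
      if (cr < thresholds$call_rate) "call_rate",
      if (maf < thresholds$maf) "maf",
      if (hw < thresholds$hwe_p) "hwe"
    )
    data.frame(snp_id = colnames(dos)[j], call_rate = cr, maf = maf,
               hwe_p = hw, pass = length(fails) == 0,
               reasons = paste(fails, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Encode a dosage vector under a genetic model
#'
#' @param dosage Vector in `{0, 1, 2, NA}` (minor allele counts).
#' @param model `"additive"` (0/1/2), `"dominant"` (carrier indicator) or
#'   `"recessive"` (minor-homozygote indicator). Missing propagates.
#' @return Numeric vector.
#' @export
#' @examples
#' encode_genetic_model(c(0, 1, 2, NA), "dominant")
encode_genetic_model <- function(dosage,
                                 model = c("additive", "dominant", "recessive")) {
  if (!is.character(model) || !all(model %in% c("additive", "dominant", "recessive")) ||
      length(model) < 1) {
    stop_mrsurv("unknown genetic model '%s'", paste(model, collapse = ","),
                class = "mrsurv_parameter_error")
  }
  model <- model[1]
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) {
    stop_mrsurv("dosage values must be 0/1/2/NA", class = "mrsurv_parameter_error")
  }
  switch(model,
         additive = as.numeric(dosage),
         dominant = as.numeric(dosage >= 1),
         recessive = as.numeric(dosage == 2))
}

# full coefficient vector of a logistic fit (used for warm starts)
logit_wald_full <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  b <- fit$coefficients
  b[!is.finite(b)] <- 0
  unname(b)
}

# Logistic maximum likelihood by damped Newton iteration (the Hessian is
# only p x p, so each step is one crossprod); Wald SE for the last
# column. Returns NA p on separation / non-convergence.
logit_wald <- function(X, y, beta_init = NULL) {
  p <- ncol(X)
  beta <- if (is.null(beta_init)) numeric(p) else beta_init
  loglik <- function(e) sum(y * e - ifelse(e > 30, e, log1p(exp(e))))
  eta <- as.numeric(X %*% beta)
  ll <- loglik(eta)
  conv <- FALSE
  delta <- rep(Inf, p)
  H <- NULL
  for (it in seq_len(40)) {
    mu <- stats::plogis(eta)
    grad <- as.numeric(crossprod(X, y - mu))
    H <- crossprod(X * sqrt(pmax(mu * (1 - mu), 1e-12)))
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) break
    delta <- backsolve(ch, forwardsolve(t(ch), grad))
    xd <- as.numeric(X %*% delta)
    step <- 1
    repeat {  # halve the step if the likelihood would decrease
      eta_new <- eta + step * xd
      lln <- loglik(eta_new)
      if (is.finite(lln) && (lln >= ll - 1e-12 || step < 1e-4)) break
      step <- step / 2
    }
    beta <- beta + step * delta
    eta <- eta_new
    done <- max(abs(step * delta)) < 1e-10 && abs(lln - ll) < 1e-12
    ll <- lln
    if (done) {
      conv <- TRUE
      break
    }
  }
  if (!conv) conv <- all(is.finite(delta)) && max(abs(delta)) < 1e-6
  mu <- stats::plogis(eta)
  if (is.null(H) || conv) {
    H <- crossprod(X * sqrt(pmax(mu * (1 - mu), 1e-12)))
  }
  # (H^-1)[p, p] = 1 / R[p, p]^2 for the Cholesky factor R of H
  cov_kk <- tryCatch(1 / chol(H)[p, p]^2, error = function(e) NA_real_)
  se <- sqrt(cov_kk)
  sep <- !conv || !is.finite(se) || se > 50 || abs(beta[p]) > 25
  if (sep) {
    return(list(beta = unname(beta[p]), se = unname(se), p = NA_real_,
                sep = TRUE))
  }
  z <- beta[p] / se
  list(beta = unname(beta[p]), se = unname(se),
       p = 2 * stats::pnorm(-abs(z)), sep = FALSE)
}

#' Three-genetic-model logistic association scan with min-P
#'
#' For each SNP, fits a maximum-likelihood logistic regression of the
#' binary phenotype on the genetic term (additive, dominant and recessive
#' codings in turn) plus covariates, reports the Wald p-value of the
#' genetic term per model, and the minimum p-value across models with the
#' best-fitting model label. Complete cases per SNP; models that are
#' monomorphic after missingness, or separate perfectly, report NA.
#'
#' The min-P across three correlated codings is anticonservative relative
#' to any single pre-specified coding; it is a screening statistic and is
#' deliberately left uncorrected.
#'
#' @param genotypes A [genotype_matrix] (QC-passing SNPs).
#' @param phenotype Binary vector (0/1 or logical), one per subject.
#' @param covariates Data frame of covariates (e.g. age, sex); character
#'   columns are expanded via `model.matrix`.
#' @param models Genetic codings to fit.
#' @return Data frame of class `association_scan`: per model beta/se/p,
#'   plus `min_p` and `best_model`.
#' @export
logistic_association_scan <- function(genotypes, phenotype, covariates = NULL,
                                      models = c("additive", "dominant", "recessive")) {
  dos <- genotypes$dosage
  y <- as.numeric(phenotype)
  if (!all(y %in% c(0, 1) | is.na(y))) {
    stop_mrsurv("phenotype must be binary 0/1", class = "mrsurv_parameter_error")
  }
  if (nrow(dos) != length(y)) {
    stop_mrsurv("genotype rows and phenotype length differ",
                class = "mrsurv_shape_error")
  }
  X0 <- if (is.null(covariates)) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = covariates)
  }
  ok0 <- !is.na(y) & stats::complete.cases(X0)
  # covariate-only fit warm-starts every per-SNP Newton iteration
  base_full <- logit_wald_full(X0[ok0, , drop = FALSE], y[ok0])
  m_snp <- ncol(dos)
  nm <- length(models)
  B <- SE <- P <- matrix(NA_real_, m_snp, nm, dimnames = list(NULL, models))
  nn <- integer(m_snp)
  no_missing <- !anyNA(dos)
  for (j in seq_len(m_snp)) {
    g_all <- dos[, j]
    cc <- if (no_missing) ok0 else ok0 & !is.na(g_all)
    nn[j] <- sum(cc)
    Xc <- cbind(X0[cc, , drop = FALSE], g = 0)
    yc <- y[cc]
    if (length(unique(yc)) < 2) next
    gc_ <- g_all[cc]
    for (mi in seq_len(nm)) {
      x <- encode_genetic_model(gc_, models[mi])
      if (length(unique(x)) < 2) next
      Xc[, ncol(Xc)] <- x
      w <- logit_wald(Xc, yc, beta_init = c(base_full, 0))
      B[j, mi] <- w$beta
      SE[j, mi] <- w$se
      P[j, mi] <- w$p
    }
  }
  min_p <- suppressWarnings(apply(P, 1, min, na.rm = TRUE))
  min_p[!is.finite(min_p)] <- NA_real_
  best <- models[apply(P, 1, function(r)
    if (all(is.na(r))) NA_integer_ else which.min(r))]
  res <- data.frame(snp_id = colnames(dos), n = nn, stringsAsFactors = FALSE)
  for (mi in seq_len(nm)) {
    res[[paste0("beta_", models[mi])]] <- B[, mi]
    res[[paste0("se_", models[mi])]] <- SE[, mi]
    res[[paste0("p_", models[mi])]] <- P[, mi]
  }
  res$min_p <- min_p
  res$best_model <- best
  if ("chrom" %in% names(genotypes$info)) {
    res$chrom <- genotypes$info$chrom
    res$pos <- genotypes$info$pos
  }
  class(res) <- c("association_scan", "data.frame")
  res
}

#' Genomic inflation factor lambda
#'
#' `lambda = median(chi-square statistics) / 0.4549364`, the median of a
#' 1-df chi-square. P-values are converted through the inverse chi-square.
#'
#' @param p P-values (used unless `chi2` given).
#' @param chi2 1-df chi-square statistics.
#' @return Lambda.
#' @export
#' @examples
#' genomic_inflation_factor(chi2 = c(1, 2, 3))  # 2 / 0.4549364
genomic_inflation_factor <- function(p = NULL, chi2 = NULL) {
  if (is.null(chi2)) {
    if (is.null(p)) {
      stop_mrsurv("supply p-values or chi-square statistics",
                  class = "mrsurv_domain_error")
    }
    chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) < 1) {
    stop_mrsurv("no finite statistics", class = "mrsurv_domain_error")
  }
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Plot-ready QQ and Manhattan tables
#'
#' No rendering: emits the tables a plotting layer would consume. The QQ
#' expected column uses the order-statistic convention
#' `-log10((i - 0.5) / n)`.
#'
#' @param results An `association_scan` data frame.
#' @param p_column Which p-value column to display (default `min_p`).
#' @return List with `qq` and `manhattan` data frames.
#' @export
qq_manhattan_tables <- function(results, p_column = "min_p") {
  p <- results[[p_column]]
  p <- p[!is.na(p)]
  n <- length(p)
  if (n < 1) {
    stop_mrsurv("no usable p-values", class = "mrsurv_domain_error")
  }
  obs <- sort(-log10(p), decreasing = TRUE)
  qq <- data.frame(
    rank = seq_len(n),
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = obs
  )
  man <- data.frame(
    snp_id = results$snp_id,
    chrom = if ("chrom" %in% names(results)) results$chrom else NA,
    pos = if ("pos" %in% names(results)) results$pos else NA,
    neg_log10_p = -log10(results[[p_column]])
  )
  list(qq = qq, manhattan = man)
}
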