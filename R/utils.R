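# Shared small helpers: argument checking, seed fan-out, deterministic I/O.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mrsurv <- function(fmt, ..., class = "mrsurv_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "mrsurv_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (length(x) == 0 && allow_zero_len) return(invisible(x))
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_mrsurv("'%s' must be finite numeric", name, class = "mrsurv_parameter_error")
  }
  if (any(x < lower) || any(x > upper)) {
    stop_mrsurv("'%s' must lie in [%s, %s]", name, format(lower), format(upper),
                class = "mrsurv_parameter_error")
  }
  invisible(x)
}

#' Derive a deterministic child seed for a named pipeline stage
#'
#' A single global seed is fanned out to per-stage seeds by hashing the stage
#' name, so any stage can be re-run in isolation and reproduce the pipeline's
#' stream. The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "gwas")
derive_seed <- function(seed, stage) {
  check_number(seed, "seed")
  seed <- as.double(seed) %% 2147483647
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((seed * 48271 + h) %% 2147483647)
}

# Fixed-format TSV writer: identical numbers -> identical bytes.
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- vapply(df[[j]], function(v) {
      if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", ...)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

# MD5 of a canonical JSON rendering; used to fingerprint run configurations.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

fmt_ci <- function(lo, hi, digits = 3) {
  sprintf("%s-%s", format(round(lo, digits), nsmall = digits),
          format(round(hi, digits), nsmall = digits))
}
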