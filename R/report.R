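# Table-style per-analysis reports: the single place where numbers are
# formatted. Stored values keep full precision; rounding happens only here.

.fmt_or <- function(x) sprintf("%.2f", round(x, 2))
.fmt_p <- function(p) {
  out <- toupper(sprintf("%.2e", p))   # e.g. 3.96E-05
  out
}

#' Build a formatted per-analysis report
#'
#' Assembles the familiar per-analysis results table — one row per method
#' with instrument count, odds ratio and 95% CI to two decimals and the
#' p-value in two-significant-digit scientific notation — together with
#' the heterogeneity and pleiotropy p-values and the per-variant
#' F-statistic range of the instruments. Formatting is locale-independent.
#'
#' @param row A `screen_row` from [run_protein()] with status `"ok"` (a
#'   non-ok row yields an empty report carrying the status).
#' @param instruments Optional `summary_stats` of the instruments used
#'   (defaults to the row's own); provides the F range.
#' @return Object of class `analysis_report`: `exposure_id`,
#'   `outcome_id`, `table` (formatted data frame), `heterogeneity_p`,
#'   `pleiotropy_p`, `f_range` (numeric min/max), `status`.
#' @export
build_report <- function(row, instruments = row$instruments) {
  if (row$status != "ok")
    return(structure(list(exposure_id = row$exposure_id,
                          outcome_id = row$outcome_id, table = NULL,
                          heterogeneity_p = NA_real_,
                          pleiotropy_p = NA_real_,
                          f_range = c(NA_real_, NA_real_),
                          status = row$status),
                     class = "analysis_report"))
  r <- row$fit$results
  tab <- data.frame(method = r$method, n_snp = r$n_snp,
                    or = .fmt_or(r$or), lcl = .fmt_or(r$lcl),
                    ucl = .fmt_or(r$ucl), p = .fmt_p(r$pvalue),
                    stringsAsFactors = FALSE)
  f <- f_statistic(instruments$records$beta, instruments$records$se)
  structure(list(exposure_id = row$exposure_id,
                 outcome_id = row$outcome_id, table = tab,
                 heterogeneity_p = row$fit$sensitivity$q_pvalue,
                 pleiotropy_p = row$fit$sensitivity$egger_intercept_p,
                 f_range = c(min(f), max(f)), status = "ok"),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("MR report: %s -> %s\n", x$exposure_id, x$outcome_id))
  if (x$status != "ok") {
    cat("  status:", x$status, "\n")
    return(invisible(x))
  }
  print(x$table, row.names = FALSE)
  cat(sprintf("F statistics: %.2f to %.2f\n", x$f_range[1], x$f_range[2]))
  if (!is.na(x$heterogeneity_p))
    cat(sprintf("Heterogeneity p: %s\n", .fmt_p(x$heterogeneity_p)))
  if (!is.na(x$pleiotropy_p))
    cat(sprintf("Pleiotropy (Egger intercept) p: %s\n",
                .fmt_p(x$pleiotropy_p)))
  invisible(x)
}

#' Write a formatted report as TSV
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(report$status == "ok")
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
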