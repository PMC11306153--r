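# Proteome-wide and phenome-wide screening drivers with
# Benjamini-Hochberg FDR control.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{k >= i} (m * p_(k) / k)` clipped
#' at 1, returned in the original order. Missing entries are excluded from
#' the family size `m` and returned as `NA`.
#'
#' @param pvalues Numeric vector with values in (0, 1] (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] <= 0 | pvalues[ok] > 1))
    stop("p-values must lie in (0, 1]")
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  q
}

#' PheWAS screening configuration
#'
#' @param min_cases Outcomes with fewer cases are excluded before any
#'   fitting (the phenome-wide case-count filter).
#' @param fdr_alpha Significance level applied to BH-adjusted p-values.
#' @return A `phewas_config` list.
#' @export
phewas_config <- function(min_cases = 50, fdr_alpha = 0.05) {
  stopifnot(min_cases >= 1, fdr_alpha > 0, fdr_alpha < 1)
  structure(list(min_cases = min_cases, fdr_alpha = fdr_alpha),
            class = "phewas_config")
}

#' Run the full MR pipeline for one protein
#'
#' Instrument selection ([select_instruments()]), outcome-overlap exclusion
#' ([exclude_outcome_associated()]), harmonization ([harmonize()]) and the
#' estimator suite ([mr_fit()]), returning one screen row. The primary
#' estimate is IVW under the multiplicative random-effects model. Failures
#' are never fatal: a protein with no surviving instrument is returned
#' with status `"no_instruments"`.
#'
#' @param exposure `summary_stats` for the protein.
#' @param gene Gene annotation row.
#' @param outcome Outcome `summary_stats`.
#' @param ld An [ld_matrix()] (or `NULL`).
#' @param sel_cfg,harm_cfg,est_cfg Configurations for the three stages.
#' @param methods Estimators to run (see [mr_fit()]).
#' @return List of class `screen_row`: `exposure_id`, `outcome_id`,
#'   `status` (`"ok"` or `"no_instruments"`), `fit` (an `mr_fit` or
#'   `NULL`), `primary` (one-row data frame or `NULL`), `instruments`.
#' @export
run_protein <- function(exposure, gene, outcome, ld = NULL,
                        sel_cfg = selection_config(),
                        harm_cfg = harmonization_config(),
                        est_cfg = estimator_config(),
                        methods = c("ivw_mre", "ivw_fe", "egger",
                                    "weighted_median", "weighted_mode",
                                    "presso")) {
  iv <- select_instruments(exposure, gene, ld, sel_cfg)
  if (nrow(iv$records) > 0L)
    iv <- exclude_outcome_associated(iv, outcome, sel_cfg)
  if (nrow(iv$records) == 0L)
    return(structure(list(exposure_id = exposure$trait_id,
                          outcome_id = outcome$trait_id,
                          status = "no_instruments", fit = NULL,
                          primary = NULL, instruments = iv),
                     class = "screen_row"))
  set <- harmonize(iv, outcome, harm_cfg)
  if (n_instruments(set) == 0L)
    return(structure(list(exposure_id = exposure$trait_id,
                          outcome_id = outcome$trait_id,
                          status = "no_instruments", fit = NULL,
                          primary = NULL, instruments = iv),
                     class = "screen_row"))
  fit <- mr_fit(set, est_cfg, methods)
  structure(list(exposure_id = exposure$trait_id,
                 outcome_id = outcome$trait_id, status = "ok", fit = fit,
                 primary = primary_result(fit), instruments = iv),
            class = "screen_row")
}

#' Proteome-wide MR screen
#'
#' Runs [run_protein()] for every exposure, then BH-adjusts the primary
#' (IVW multiplicative random effects) p-values across all proteins with
#' an `ok` fit — that set is the FDR family. Returns per-protein rows plus
#' summary counts and a volcano-ready table (`beta`, `-log10 p`).
#'
#' @param exposures List of `summary_stats`, one per protein.
#' @param genes Gene-annotation data frame (matched to exposures by
#'   `gene_id` = trait id).
#' @param outcome Outcome `summary_stats`.
#' @param ld An [ld_matrix()] or `NULL`.
#' @param sel_cfg,harm_cfg,est_cfg Stage configurations.
#' @param methods Estimators to run per protein.
#' @param fdr_alpha Level used for the reported significance counts.
#' @param log_path Optional path; when given, a JSON-lines run log is
#'   written — one header line with the thresholds and the estimator
#'   seed, then one line per protein with its status and primary
#'   estimate.
#' @return Object of class `mr_screen`: `results` (data frame, one row per
#'   protein: ids, `status`, `n_snp`, `beta`, `se`, `or`, `lcl`, `ucl`,
#'   `pvalue`, `p_fdr`, `q`, `q_pvalue`, `egger_intercept_p`,
#'   `presso_global_p`), `rows` (the `screen_row` objects), `summary`
#'   (counts), `volcano` (data frame `exposure_id`, `beta`,
#'   `neg_log10_p`).
#' @export
run_proteome <- function(exposures, genes, outcome, ld = NULL,
                         sel_cfg = selection_config(),
                         harm_cfg = harmonization_config(),
                         est_cfg = estimator_config(),
                         methods = c("ivw_mre", "ivw_fe", "egger",
                                     "weighted_median", "weighted_mode",
                                     "presso"),
                         fdr_alpha = 0.05, log_path = NULL) {
  if (length(exposures) == 0L) stop("empty exposure list")
  rows <- lapply(exposures, function(ex) {
    gene <- genes[genes$gene_id == ex$trait_id, , drop = FALSE]
    if (nrow(gene) == 0L)
      stop("no gene annotation for exposure ", ex$trait_id)
    run_protein(ex, gene[1L, ], outcome, ld, sel_cfg, harm_cfg, est_cfg,
                methods)
  })
  ok_row <- vapply(rows, function(r) r$status == "ok", logical(1))
  g_num <- function(get) vapply(rows, function(r)
    if (r$status == "ok") get(r) else NA_real_, numeric(1))
  res <- .df(
    exposure_id = vapply(rows, `[[`, character(1), "exposure_id"),
    outcome_id = vapply(rows, `[[`, character(1), "outcome_id"),
    status = vapply(rows, `[[`, character(1), "status"),
    n_snp = ifelse(ok_row,
                   vapply(rows, function(r)
                     if (r$status == "ok") r$primary$n_snp else 0L,
                     integer(1)), 0L),
    beta = g_num(function(r) r$primary$beta),
    se = g_num(function(r) r$primary$se),
    or = g_num(function(r) r$primary$or),
    lcl = g_num(function(r) r$primary$lcl),
    ucl = g_num(function(r) r$primary$ucl),
    pvalue = g_num(function(r) r$primary$pvalue),
    q = g_num(function(r) r$fit$sensitivity$q),
    q_pvalue = g_num(function(r) r$fit$sensitivity$q_pvalue),
    egger_intercept_p = g_num(function(r)
      r$fit$sensitivity$egger_intercept_p),
    presso_global_p = g_num(function(r)
      r$fit$sensitivity$presso_global_p))
  res$p_fdr <- bh_fdr(ifelse(res$status == "ok", res$pvalue, NA))
  ok <- res$status == "ok"
  summary <- list(n_proteins = length(exposures),
                  n_ok = sum(ok),
                  n_no_instruments = sum(res$status == "no_instruments"),
                  n_nominal = sum(res$pvalue[ok] < 0.05),
                  n_fdr = sum(res$p_fdr[ok] < fdr_alpha),
                  fdr_family_size = sum(ok))
  volcano <- data.frame(exposure_id = res$exposure_id[ok],
                        beta = res$beta[ok],
                        neg_log10_p = -log10(res$pvalue[ok]),
                        stringsAsFactors = FALSE)
  if (!is.null(log_path)) {
    con <- file(log_path, open = "wt")
    writeLines(sprintf(
      paste0('{"event":"config","p_threshold":%.3g,"cis_window":%g,',
             '"clump_r2":%g,"f_min":%g,"fdr_alpha":%g,"seed":%s}'),
      sel_cfg$p_threshold, sel_cfg$cis_window, sel_cfg$clump_r2,
      sel_cfg$f_min, fdr_alpha,
      if (is.null(est_cfg$seed)) "null" else format(est_cfg$seed)), con)
    writeLines(sprintf(
      '{"event":"protein","id":"%s","status":"%s","n_snp":%d,"pvalue":%s}',
      res$exposure_id, res$status, res$n_snp,
      ifelse(is.na(res$pvalue), "null", sprintf("%.6g", res$pvalue))),
      con)
    close(con)
  }
  structure(list(results = res, rows = rows, summary = summary,
                 volcano = volcano),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<mr_screen> %d proteins: %d fitted, %d without ",
                     "instruments\n  p < 0.05: %d; FDR-significant: %d ",
                     "(family m = %d)\n"),
              s$n_proteins, s$n_ok, s$n_no_instruments, s$n_nominal,
              s$n_fdr, s$fdr_family_size))
  invisible(x)
}

#' Phenome-wide MR screen for one protein
#'
#' Fits the protein's instruments against many outcomes. Outcomes with
#' fewer than `cfg$min_cases` cases are excluded before any fitting;
#' instruments are re-harmonized (and outcome-overlap-excluded) per
#' outcome; BH-FDR is applied across the retained outcomes.
#'
#' @param instruments `summary_stats` of the protein's selected
#'   instruments (from [select_instruments()]).
#' @param outcomes List of binary-trait `summary_stats`, each carrying
#'   `n_cases`; ids must be unique.
#' @param cfg A [phewas_config()].
#' @param sel_cfg,harm_cfg,est_cfg Stage configurations.
#' @param methods Estimators to run per outcome (default IVW only, the
#'   screen's primary).
#' @return Object of class `mr_phewas`: `results` (one row per retained
#'   outcome with `n_cases`, primary estimate, `p_fdr`), `excluded`
#'   (ids dropped by the case filter), `manhattan` (data frame
#'   `outcome_id`, `neg_log10_p`).
#' @export
run_phewas <- function(instruments, outcomes, cfg = phewas_config(),
                       sel_cfg = selection_config(),
                       harm_cfg = harmonization_config(),
                       est_cfg = estimator_config(),
                       methods = "ivw_mre") {
  ids <- vapply(outcomes, function(o) o$trait_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate outcome ids")
  n_cases <- vapply(outcomes, function(o) as.numeric(o$n_cases),
                    numeric(1))
  keep <- !is.na(n_cases) & n_cases >= cfg$min_cases
  excluded <- ids[!keep]
  outcomes <- outcomes[keep]

  rows <- lapply(outcomes, function(out) {
    iv <- exclude_outcome_associated(instruments, out, sel_cfg)
    if (nrow(iv$records) == 0L)
      return(data.frame(outcome_id = out$trait_id,
                        n_cases = out$n_cases, status = "no_instruments",
                        n_snp = 0L, beta = NA_real_, se = NA_real_,
                        or = NA_real_, lcl = NA_real_, ucl = NA_real_,
                        pvalue = NA_real_, stringsAsFactors = FALSE))
    set <- harmonize(iv, out, harm_cfg)
    if (n_instruments(set) == 0L)
      return(data.frame(outcome_id = out$trait_id,
                        n_cases = out$n_cases, status = "no_instruments",
                        n_snp = 0L, beta = NA_real_, se = NA_real_,
                        or = NA_real_, lcl = NA_real_, ucl = NA_real_,
                        pvalue = NA_real_, stringsAsFactors = FALSE))
    pr <- primary_result(mr_fit(set, est_cfg, methods))
    data.frame(outcome_id = out$trait_id, n_cases = out$n_cases,
               status = "ok", n_snp = pr$n_snp, beta = pr$beta,
               se = pr$se, or = pr$or, lcl = pr$lcl, ucl = pr$ucl,
               pvalue = pr$pvalue, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_fdr <- bh_fdr(ifelse(res$status == "ok", res$pvalue, NA))
  ok <- res$status == "ok"
  structure(list(results = res, excluded = excluded,
                 manhattan = data.frame(outcome_id = res$outcome_id[ok],
                                        neg_log10_p =
                                          -log10(res$pvalue[ok]),
                                        stringsAsFactors = FALSE),
                 config = cfg),
            class = "mr_phewas")
}

#' @export
print.mr_phewas <- function(x, ...) {
  ok <- x$results$status == "ok"
  cat(sprintf(paste0("<mr_phewas> %d outcomes fitted (%d excluded below ",
                     "%d cases)\n  p < 0.05: %d; FDR-significant: %d\n"),
              sum(ok), length(x$excluded), x$config$min_cases,
              sum(x$results$pvalue[ok] < 0.05),
              sum(x$results$p_fdr[ok] < x$config$fdr_alpha)))
  invisible(x)
}

#' Write screen results as TSV
#'
#' @param screen An `mr_screen` or `mr_phewas`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_screen_results <- function(screen, path) {
  utils::write.table(screen$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
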