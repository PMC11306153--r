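# The central fitting function: run the estimator and sensitivity suite on
# one harmonized instrument set and return a classed model object.

#' Fit the two-sample MR estimator suite to an instrument set
#'
#' Runs every requested estimator the instrument count admits — IVW under
#' the multiplicative random-effects model (the primary estimate) and the
#' fixed-effect model, MR-Egger (L >= 3), weighted median and weighted mode
#' (L >= 3), the single-instrument Wald ratio — together with the
#' sensitivity suite: Cochran's Q (L >= 2), the MR-Egger intercept test,
#' and MR-PRESSO (L >= 4). Stochastic components (bootstrap SEs, PRESSO
#' null draws) require `cfg$seed`; given the same seed the fit is
#' byte-reproducible.
#'
#' @param set An [instrument_set()], normally from [harmonize()].
#' @param cfg An [estimator_config()].
#' @param methods Estimators to run, a subset of `c("ivw_mre", "ivw_fe",
#'   "egger", "weighted_median", "weighted_mode", "wald", "presso")`.
#'   Methods whose instrument requirement is not met are skipped silently
#'   (recorded in `skipped`).
#' @return An object of class `mr_fit`: list with `exposure_id`,
#'   `outcome_id`, `n_snp`, `results` (one row per estimator: `method`,
#'   `n_snp`, `beta`, `se`, `or`, `lcl`, `ucl`, `pvalue`), `sensitivity`
#'   (Q, Egger intercept, PRESSO fields), `skipped`, `set`, `config`.
#' @seealso [ivw()], [mr_egger()], [weighted_median()], [weighted_mode()],
#'   [mr_presso()], [cochran_q()]
#' @examples
#' set <- instrument_set("PROT", "disease", data.frame(
#'   variant_id = paste0("rs", 1:5),
#'   beta_x = c(0.30, 0.25, 0.40, 0.35, 0.28), se_x = 0.02,
#'   beta_y = c(0.10, 0.09, 0.13, 0.12, 0.10), se_y = 0.03))
#' fit <- mr_fit(set, estimator_config(seed = 1))
#' print(fit)
#' coef(fit)
#' @export
mr_fit <- function(set, cfg = estimator_config(),
                   methods = c("ivw_mre", "ivw_fe", "egger",
                               "weighted_median", "weighted_mode",
                               "wald", "presso")) {
  stopifnot(inherits(set, "instrument_set"))
  L <- n_instruments(set)
  if (L == 0L) stop("no instruments in set")
  known <- c("ivw_mre", "ivw_fe", "egger", "weighted_median",
             "weighted_mode", "wald", "presso")
  stopifnot(all(methods %in% known))

  rows <- list()
  skipped <- character()
  sens <- list(q = NA_real_, q_df = NA_integer_, q_pvalue = NA_real_,
               egger_intercept = NA_real_, egger_intercept_se = NA_real_,
               egger_intercept_p = NA_real_, presso_global_p = NA_real_,
               presso_outliers = character())

  if ("wald" %in% methods && L == 1L)
    rows$wald <- wald_ratio(set$pairs[1L, ], cfg$ci_level)
  if ("ivw_mre" %in% methods) rows$ivw_mre <- ivw(set, "mre", cfg)
  if ("ivw_fe" %in% methods) rows$ivw_fe <- ivw(set, "fe", cfg)

  if (L >= 2L) {
    cq <- cochran_q(set)
    sens[c("q", "q_df", "q_pvalue")] <- cq
  }
  if ("egger" %in% methods) {
    eg <- if (L >= 3L) suppressMessages(mr_egger(set, cfg)) else NULL
    if (is.null(eg)) skipped <- c(skipped, "egger")
    else {
      rows$egger <- eg$result
      sens$egger_intercept <- eg$egger_intercept
      sens$egger_intercept_se <- eg$egger_intercept_se
      sens$egger_intercept_p <- eg$egger_intercept_p
    }
  }
  for (m in c("weighted_median", "weighted_mode")) {
    if (!m %in% methods) next
    fun <- if (m == "weighted_median") weighted_median else weighted_mode
    r <- if (L >= 3L) suppressMessages(fun(set, cfg)) else NULL
    if (is.null(r)) skipped <- c(skipped, m) else rows[[m]] <- r
  }
  if ("presso" %in% methods) {
    pr <- if (L >= 4L) suppressMessages(mr_presso(set, cfg)) else NULL
    if (is.null(pr)) skipped <- c(skipped, "presso")
    else {
      sens$presso_global_p <- pr$presso_global_p
      sens$presso_outliers <- pr$presso_outliers
      if (!is.null(pr$corrected)) rows$presso_corrected <- pr$corrected
    }
  }

  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(exposure_id = set$exposure_id,
                 outcome_id = set$outcome_id, n_snp = L,
                 results = results, sensitivity = sens,
                 skipped = skipped, set = set, config = cfg),
            class = "mr_fit")
}

#' Primary causal estimate of an `mr_fit`
#'
#' The multiplicative random-effects IVW row (or the first available row
#' when IVW-MRE was not run).
#'
#' @param fit An `mr_fit`.
#' @return One-row data frame.
#' @export
primary_result <- function(fit) {
  r <- fit$results
  if ("ivw_mre" %in% r$method) r[r$method == "ivw_mre", ] else r[1L, ]
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d instruments)\n",
              x$exposure_id, x$outcome_id, x$n_snp))
  r <- x$results
  show <- data.frame(method = r$method, n_snp = r$n_snp,
                     OR = round(r$or, digits),
                     `95% CI` = sprintf("[%.*f, %.*f]", digits, r$lcl,
                                        digits, r$ucl),
                     p = signif(r$pvalue, digits),
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  s <- f$sensitivity
  if (!is.na(s$q))
    cat(sprintf("Heterogeneity: Cochran Q = %.3f (df %d), p = %.3g\n",
                s$q, s$q_df, s$q_pvalue))
  if (!is.na(s$egger_intercept))
    cat(sprintf("Pleiotropy: Egger intercept = %.4g (SE %.4g), p = %.3g\n",
                s$egger_intercept, s$egger_intercept_se,
                s$egger_intercept_p))
  if (!is.na(s$presso_global_p))
    cat(sprintf("MR-PRESSO global p = %.3g; outliers: %s\n",
                s$presso_global_p,
                if (length(s$presso_outliers)) paste(s$presso_outliers,
                                                     collapse = ", ")
                else "none"))
  if (length(f$skipped))
    cat("Skipped (too few instruments):",
        paste(f$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$beta, object$results$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  r <- object$results
  z <- stats::qnorm((1 + level) / 2)
  ci <- cbind(r$beta - z * r$se, r$beta + z * r$se)
  dimnames(ci) <- list(r$method,
                       sprintf("%.1f %%", c((1 - level) / 2,
                                            (1 + level) / 2) * 100))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Write the per-method results of a fit as TSV
#'
#' One row per (exposure, outcome, method) with `n_snp`, `beta`, `se`,
#' `or`, `lcl`, `ucl`, `p`.
#'
#' @param fit An `mr_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mr_results <- function(fit, path) {
  r <- fit$results
  out <- cbind(exposure_id = fit$exposure_id, outcome_id = fit$outcome_id,
               r)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
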