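# Two-sample MR estimators and sensitivity analyses: Wald ratio, IVW
# (fixed and multiplicative random effects), Cochran's Q, MR-Egger with
# intercept test, weighted median, weighted mode, MR-PRESSO.
#
# Conventions: ratio-scale first-order weights w_j = beta_x_j^2 / se_y_j^2
# (se_x enters only through the bootstrap and MR-PRESSO resampling);
# two-sided p-values, floored at the smallest positive double; Egger
# p-values from t(L - 2), all others from the normal.

#' Estimator configuration
#'
#' Tuning constants for the stochastic estimators. All resampling is seeded
#' and single-threaded: the same seed yields byte-identical output.
#'
#' @param bootstrap_iterations Parametric bootstrap replicates for the
#'   weighted-median / weighted-mode standard errors.
#' @param presso_simulations Simulated datasets for the MR-PRESSO null
#'   distribution.
#' @param mode_bandwidth_multiplier Multiplier on the rule-of-thumb kernel
#'   bandwidth of the weighted mode.
#' @param seed Integer seed; must be set before calling any stochastic
#'   estimator.
#' @param ci_level Confidence level for odds-ratio intervals.
#' @param mre_floor Keep the multiplicative random-effects SE at or above
#'   the fixed-effect SE (the conventional floor); set `FALSE` to let
#'   under-dispersion shrink it.
#' @return An `estimator_config` list.
#' @export
estimator_config <- function(bootstrap_iterations = 1000,
                             presso_simulations = 1000,
                             mode_bandwidth_multiplier = 1, seed = NULL,
                             ci_level = 0.95, mre_floor = TRUE) {
  stopifnot(bootstrap_iterations >= 100, presso_simulations >= 100,
            mode_bandwidth_multiplier > 0, ci_level > 0, ci_level < 1)
  structure(list(bootstrap_iterations = as.integer(bootstrap_iterations),
                 presso_simulations = as.integer(presso_simulations),
                 mode_bandwidth_multiplier = mode_bandwidth_multiplier,
                 seed = seed, ci_level = ci_level, mre_floor = mre_floor),
            class = "estimator_config")
}

.require_seed <- function(cfg, what) {
  if (is.null(cfg$seed))
    stop(what, " is stochastic: set estimator_config(seed = ...)")
}

.pnorm2 <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

#' Convert a log-odds effect to an odds ratio with confidence interval
#'
#' `exp(beta)` with Wald limits `exp(beta -/+ z * se)` at the normal
#' quantile for `ci_level`.
#'
#' @param beta Effect on the log-odds scale.
#' @param se Standard error (>= 0).
#' @param ci_level Confidence level.
#' @return Named list `or_point`, `or_lcl`, `or_ucl` (vectorized).
#' @export
to_odds_ratio <- function(beta, se, ci_level = 0.95) {
  z <- stats::qnorm((1 + ci_level) / 2)
  list(or_point = exp(beta), or_lcl = exp(beta - z * se),
       or_ucl = exp(beta + z * se))
}

# One result row shared by all estimators.
.mr_result <- function(method, n_snp, beta, se, ci_level = 0.95,
                       pvalue = NULL) {
  if (is.null(pvalue)) pvalue <- .pnorm2(beta / se)
  or <- to_odds_ratio(beta, se, ci_level)
  .df(method = method, n_snp = as.integer(n_snp), beta = beta,
      se = se, or = or$or_point, lcl = or$or_lcl, ucl = or$or_ucl,
      pvalue = max(pvalue, .Machine$double.xmin))
}

.ratios <- function(set) set$pairs$beta_y / set$pairs$beta_x
.ivw_weights <- function(set) set$pairs$beta_x^2 / set$pairs$se_y^2

#' Wald ratio estimate for a single instrument
#'
#' The per-variant causal estimate `beta_y / beta_x` with first-order
#' standard error `se_y / |beta_x|` and a two-sided normal p-value.
#'
#' @param pair One instrument: a list or one-row data frame with `beta_x`,
#'   `beta_y`, `se_y` (and optionally `variant_id`).
#' @param ci_level Confidence level for the odds-ratio interval.
#' @return One-row data frame (`method`, `n_snp`, `beta`, `se`, `or`,
#'   `lcl`, `ucl`, `pvalue`).
#' @export
wald_ratio <- function(pair, ci_level = 0.95) {
  if (pair$beta_x == 0) stop("Wald ratio undefined for beta_x = 0")
  .mr_result("wald", 1L, pair$beta_y / pair$beta_x,
             pair$se_y / abs(pair$beta_x), ci_level)
}

#' Inverse-variance-weighted estimate
#'
#' Combines per-variant Wald ratios with first-order inverse-variance
#' weights `w_j = beta_x_j^2 / se_y_j^2`; algebraically identical to the
#' zero-intercept weighted regression of `beta_y` on `beta_x` with weights
#' `1/se_y^2`. The fixed-effect SE is `(sum w_j)^(-1/2)`; under the
#' multiplicative random-effects model it is inflated by
#' `sqrt(Q / (L - 1))` (floored at 1 by default), with Q Cochran's
#' heterogeneity statistic. A single-instrument set reduces to the Wald
#' ratio whatever the model.
#'
#' @param set An `instrument_set` with at least one instrument.
#' @param model `"mre"` (multiplicative random effects, the primary model)
#'   or `"fe"` (fixed effect).
#' @param cfg An [estimator_config()] (CI level and MRE floor).
#' @return One-row result data frame as in [wald_ratio()], method
#'   `"ivw_mre"` or `"ivw_fe"`.
#' @export
ivw <- function(set, model = c("mre", "fe"), cfg = estimator_config()) {
  model <- match.arg(model)
  L <- n_instruments(set)
  if (L == 0L) stop("no instruments: IVW requires at least one")
  if (L == 1L) {
    res <- wald_ratio(set$pairs[1L, ], cfg$ci_level)
    res$method <- paste0("ivw_", model)
    return(res)
  }
  w <- .ivw_weights(set)
  th <- .ratios(set)
  est <- sum(w * th) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (model == "mre") {
    q <- sum(w * (th - est)^2)
    scale <- sqrt(q / (L - 1))
    if (cfg$mre_floor) scale <- max(1, scale)
    se <- se * scale
  }
  .mr_result(paste0("ivw_", model), L, est, se, cfg$ci_level)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (theta_j - theta_fe)^2` over the per-variant ratio
#' estimates, referred to a chi-square with `L - 1` degrees of freedom.
#' Undefined (reported as `NA`) for fewer than two instruments.
#'
#' @param set An `instrument_set`.
#' @return List with `q`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(set) {
  L <- n_instruments(set)
  if (L < 2L) return(list(q = NA_real_, q_df = NA_integer_,
                          q_pvalue = NA_real_))
  w <- .ivw_weights(set)
  th <- .ratios(set)
  est <- sum(w * th) / sum(w)
  q <- sum(w * (th - est)^2)
  list(q = q, q_df = L - 1L,
       q_pvalue = stats::pchisq(q, df = L - 1, lower.tail = FALSE))
}

# Closed-form weighted least squares of y on (1, x); returns coefficients,
# their SEs (scaled by max(1, residual scale)) and t p-values on df = L - 2.
.wls_line <- function(x, y, w, scale_floor = TRUE) {
  L <- length(x)
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  d <- sw * sxx - swx^2
  slope <- (sw * sxy - swx * swy) / d
  inter <- (swy * sxx - swx * sxy) / d
  resid <- y - inter - slope * x
  sigma2 <- sum(w * resid^2) / (L - 2)
  scale2 <- if (scale_floor) max(1, sigma2) else sigma2
  se_slope <- sqrt(scale2 * sw / d)
  se_inter <- sqrt(scale2 * sxx / d)
  list(slope = slope, intercept = inter, se_slope = se_slope,
       se_intercept = se_inter, df = L - 2, sigma2 = sigma2)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with a free
#' intercept (weights `1/se_y^2`), after orienting all exposure effects
#' positive. The slope is the pleiotropy-adjusted causal estimate; a
#' non-zero intercept indicates directional horizontal pleiotropy (valid
#' under the InSIDE assumption). Standard errors carry the multiplicative
#' overdispersion factor `max(1, residual scale)`; p-values use a t
#' distribution on `L - 2` degrees of freedom. Requires at least three
#' instruments.
#'
#' @param set An `instrument_set` (not mutated: orientation is internal).
#' @param cfg An [estimator_config()].
#' @return List with `result` (slope row, method `"egger"`) and the
#'   intercept fields `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`; `NULL` if fewer than 3 instruments.
#' @export
mr_egger <- function(set, cfg = estimator_config()) {
  L <- n_instruments(set)
  if (L < 3L) {
    message("MR-Egger skipped: needs >= 3 instruments, have ", L)
    return(NULL)
  }
  o <- orient_positive_exposure(set)
  fit <- .wls_line(o$pairs$beta_x, o$pairs$beta_y, 1 / o$pairs$se_y^2)
  p_slope <- 2 * stats::pt(-abs(fit$slope / fit$se_slope), df = fit$df)
  p_inter <- 2 * stats::pt(-abs(fit$intercept / fit$se_intercept),
                           df = fit$df)
  list(result = .mr_result("egger", L, fit$slope, fit$se_slope,
                           cfg$ci_level,
                           pvalue = max(p_slope, .Machine$double.xmin)),
       egger_intercept = fit$intercept,
       egger_intercept_se = fit$se_intercept,
       egger_intercept_p = max(p_inter, .Machine$double.xmin))
}

# Weighted median of `values` with weights `w`: sort, accumulate the
# normalized weights to their interval midpoints, interpolate at 0.5.
.weighted_median_point <- function(values, w) {
  o <- order(values)
  v <- values[o]
  wn <- w[o] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1]) return(v[1])
  if (0.5 >= s[length(s)]) return(v[length(s)])
  stats::approx(s, v, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap of a point estimator over instrument resamples.
.bootstrap_se <- function(set, cfg, point_fun) {
  p <- set$pairs
  L <- nrow(p)
  B <- cfg$bootstrap_iterations
  withr::with_seed(cfg$seed, {
    bx <- matrix(stats::rnorm(B * L, mean = rep(p$beta_x, each = B),
                              sd = rep(p$se_x, each = B)), nrow = B)
    by <- matrix(stats::rnorm(B * L, mean = rep(p$beta_y, each = B),
                              sd = rep(p$se_y, each = B)), nrow = B)
    est <- vapply(seq_len(B), function(b) {
      th <- by[b, ] / bx[b, ]
      w <- bx[b, ]^2 / p$se_y^2
      point_fun(th, w)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted-median estimate
#'
#' The inverse-variance weighted median of the per-variant Wald ratios:
#' consistent when instruments carrying at least half of the weight are
#' valid. The point estimate interpolates the sorted ratios at the 50%
#' point of the cumulative normalized weights (taken at their interval
#' midpoints); the standard error is the spread of the estimate over
#' seeded parametric bootstrap resamples of both effect estimates; the
#' p-value is two-sided normal. Requires at least three instruments.
#'
#' @param set An `instrument_set`.
#' @param cfg An [estimator_config()] with `seed` set.
#' @return One-row result data frame, method `"weighted_median"`; `NULL`
#'   if fewer than 3 instruments.
#' @export
weighted_median <- function(set, cfg = estimator_config()) {
  L <- n_instruments(set)
  if (L < 3L) {
    message("weighted median skipped: needs >= 3 instruments, have ", L)
    return(NULL)
  }
  .require_seed(cfg, "weighted_median")
  est <- .weighted_median_point(.ratios(set), .ivw_weights(set))
  se <- .bootstrap_se(set, cfg, .weighted_median_point)
  .mr_result("weighted_median", L, est, se, cfg$ci_level)
}

# Weighted-mode point estimate: argmax of a weighted Gaussian KDE of the
# ratios. Returns the common value when the bandwidth degenerates.
.weighted_mode_point <- function(values, w, bw_mult = 1) {
  L <- length(values)
  s <- stats::sd(values)
  iqr <- stats::IQR(values)
  h <- bw_mult * 0.9 * min(s, iqr / 1.34) * L^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(values[which.max(w)])
  d <- stats::density(values, weights = w / sum(w), bw = h, n = 1024,
                      from = min(values) - 3 * h, to = max(values) + 3 * h)
  d$x[which.max(d$y)]
}

#' Weighted-mode estimate
#'
#' The mode of the smoothed, weight-carrying distribution of per-variant
#' Wald ratios: consistent when the largest group of instruments sharing
#' the same ratio is valid. The kernel bandwidth follows the modified
#' Silverman rule `0.9 min(sd, IQR/1.34) L^(-1/5)` on the ratios, scaled
#' by `mode_bandwidth_multiplier`; the SE comes from the same parametric
#' bootstrap as the weighted median. Requires at least three instruments.
#'
#' @inheritParams weighted_median
#' @return One-row result data frame, method `"weighted_mode"`; `NULL` if
#'   fewer than 3 instruments.
#' @export
weighted_mode <- function(set, cfg = estimator_config()) {
  L <- n_instruments(set)
  if (L < 3L) {
    message("weighted mode skipped: needs >= 3 instruments, have ", L)
    return(NULL)
  }
  .require_seed(cfg, "weighted_mode")
  bm <- cfg$mode_bandwidth_multiplier
  est <- .weighted_mode_point(.ratios(set), .ivw_weights(set), bm)
  se <- .bootstrap_se(set, cfg,
                      function(th, w) .weighted_mode_point(th, w, bm))
  .mr_result("weighted_mode", L, est, se, cfg$ci_level)
}

# Leave-one-out IVW (fixed-effect) estimates from sufficient sums;
# x, y vectors (or matrices with simulations in rows), w0 = 1/se_y^2.
.loo_ivw <- function(x, y, w0) {
  if (is.matrix(x)) {
    sxy <- rowSums(sweep(x * y, 2, w0, `*`))
    sxx <- rowSums(sweep(x^2, 2, w0, `*`))
    (sxy - sweep(x * y, 2, w0, `*`)) / (sxx - sweep(x^2, 2, w0, `*`))
  } else {
    sxy <- sum(w0 * x * y)
    sxx <- sum(w0 * x^2)
    (sxy - w0 * x * y) / (sxx - w0 * x^2)
  }
}

#' MR-PRESSO global pleiotropy test and outlier detection
#'
#' Residual-sum-of-squares test for pleiotropic outliers. The observed
#' statistic is `RSS = sum_j (beta_y_j - theta_(-j) * beta_x_j)^2 / se_y_j^2`
#' with `theta_(-j)` the leave-one-out fixed-effect IVW estimate. Its null
#' distribution is built from seeded parametric draws
#' `beta_x* ~ N(beta_x, se_x)`, `beta_y* ~ N(theta_(-j) beta_x, se_y)`,
#' recomputing the leave-one-out estimates and the RSS on each draw. The
#' global p is the proportion of simulated RSS at or above the observed
#' one; per-variant outlier p-values compare each observed weighted
#' residual with its simulated distribution, Bonferroni-adjusted by L and
#' flagged below 0.05. When outliers are flagged, an outlier-corrected
#' IVW (multiplicative random effects) estimate on the remaining
#' instruments is returned. Requires at least four instruments.
#'
#' @param set An `instrument_set`.
#' @param cfg An [estimator_config()] with `seed` set.
#' @return List with `presso_global_p`, `presso_outliers` (variant ids),
#'   `outlier_p` (adjusted, named), and `corrected` (one-row result data
#'   frame, method `"presso_corrected"`, or `NULL`); `NULL` if fewer than
#'   4 instruments.
#' @export
mr_presso <- function(set, cfg = estimator_config()) {
  L <- n_instruments(set)
  if (L < 4L) {
    message("MR-PRESSO skipped: needs >= 4 instruments, have ", L)
    return(NULL)
  }
  .require_seed(cfg, "mr_presso")
  p <- set$pairs
  w0 <- 1 / p$se_y^2
  th_loo <- .loo_ivw(p$beta_x, p$beta_y, w0)
  resid_obs <- w0 * (p$beta_y - th_loo * p$beta_x)^2
  rss_obs <- sum(resid_obs)

  S <- cfg$presso_simulations
  withr::with_seed(cfg$seed, {
    xs <- matrix(stats::rnorm(S * L, mean = rep(p$beta_x, each = S),
                              sd = rep(p$se_x, each = S)), nrow = S)
    ys <- matrix(stats::rnorm(S * L, mean = rep(th_loo * p$beta_x, each = S),
                              sd = rep(p$se_y, each = S)), nrow = S)
  })
  th_loo_s <- .loo_ivw(xs, ys, w0)
  resid_s <- sweep((ys - th_loo_s * xs)^2, 2, w0, `*`)
  rss_s <- rowSums(resid_s)
  global_p <- mean(rss_s >= rss_obs)
  outlier_p <- pmin(1, colMeans(sweep(resid_s, 2, resid_obs, `>=`)) * L)
  names(outlier_p) <- p$variant_id
  outliers <- p$variant_id[outlier_p < 0.05]

  corrected <- NULL
  if (length(outliers) > 0 && L - length(outliers) >= 1) {
    sub <- set
    sub$pairs <- p[!p$variant_id %in% outliers, , drop = FALSE]
    corrected <- ivw(sub, "mre", cfg)
    corrected$method <- "presso_corrected"
  }
  list(presso_global_p = global_p, presso_outliers = outliers,
       outlier_p = outlier_p, corrected = corrected)
}
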