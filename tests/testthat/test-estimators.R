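# Estimator suite: closed-form fixtures, independent WLS/meta oracles,
# distributional checks, determinism contracts.

test_that("Wald ratio is exact arithmetic with a first-order SE", {
  r <- wald_ratio(list(beta_x = 0.5, beta_y = 0.25, se_y = 0.05))
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1)
  r0 <- wald_ratio(list(beta_x = 0.5, beta_y = 0, se_y = 0.05))
  expect_equal(r0$beta, 0)
  expect_equal(r0$pvalue, 1)
  expect_error(wald_ratio(list(beta_x = 0, beta_y = 1, se_y = 1)),
               "beta_x")
  withr::with_seed(2, {
    for (i in 1:20) {
      bx <- rnorm(1); by <- rnorm(1); sy <- runif(1, 0.01, 1)
      if (abs(bx) < 1e-3) next
      r <- wald_ratio(list(beta_x = bx, beta_y = by, se_y = sy))
      expect_equal(r$beta, by / bx)
      expect_equal(r$se, sy / abs(bx))
    }
  })
})

test_that("IVW averages equal-weight ratios and reduces to Wald at L = 1", {
  set <- make_set(c(1, 1), c(0.2, 0.4), se_y = 1)
  expect_equal(ivw(set, "fe")$beta, 0.3)
  one <- make_set(0.5, 0.25, se_y = 0.05)
  w <- wald_ratio(one$pairs[1, ])
  for (model in c("fe", "mre")) {
    r <- ivw(one, model)
    expect_equal(r$beta, w$beta)
    expect_equal(r$se, w$se)
  }
  expect_error(ivw(make_set(numeric(0), numeric(0))), "no instruments")
})

test_that("IVW-fe equals the fixed-effect meta-analysis and zero-intercept
           WLS; Egger equals generic WLS (independent oracles)", {
  for (i in 1:50) {
    L <- sample(3:20, 1)
    set <- random_set(L, seed = 1000 + i)
    p <- set$pairs
    fe <- ivw(set, "fe")
    # oracle 1: inverse-variance meta-analysis of the Wald ratios
    meta <- metafor::rma(yi = p$beta_y / p$beta_x,
                         sei = p$se_y / abs(p$beta_x), method = "FE")
    expect_equal(fe$beta, as.numeric(meta$beta), tolerance = 1e-10)
    expect_equal(fe$se, meta$se, tolerance = 1e-10)
    # oracle 2: zero-intercept weighted least squares
    wls <- lm(beta_y ~ 0 + beta_x, data = p, weights = 1 / p$se_y^2)
    expect_equal(fe$beta, unname(coef(wls)), tolerance = 1e-10)
    expect_equal(fe$se,
                 unname(sqrt(diag(vcov(wls)))) / summary(wls)$sigma,
                 tolerance = 1e-10)
    # Egger vs a generic WLS oracle (after positive orientation)
    o <- orient_positive_exposure(set)$pairs
    eg <- mr_egger(set)
    lmfit <- lm(beta_y ~ beta_x, data = o, weights = 1 / o$se_y^2)
    expect_equal(eg$result$beta, unname(coef(lmfit)[2]),
                 tolerance = 1e-10)
    expect_equal(eg$egger_intercept, unname(coef(lmfit)[1]),
                 tolerance = 1e-10)
    sig <- summary(lmfit)$sigma
    se_lm <- sqrt(diag(vcov(lmfit))) / sig * max(1, sig)
    expect_equal(eg$result$se, unname(se_lm[2]), tolerance = 1e-10)
    expect_equal(eg$egger_intercept_se, unname(se_lm[1]),
                 tolerance = 1e-10)
  }
})

test_that("multiplicative random effects inflate but never deflate the SE", {
  set <- random_set(10, seed = 4)
  fe <- ivw(set, "fe")
  mre <- ivw(set, "mre")
  expect_gte(mre$se, fe$se)
  expect_equal(mre$beta, fe$beta)
  q <- cochran_q(set)
  expect_equal(mre$se / fe$se, max(1, sqrt(q$q / (q$q_df))),
               tolerance = 1e-12)
  # without the floor the scale is exactly sqrt(Q / (L - 1))
  nofloor <- ivw(set, "mre", estimator_config(mre_floor = FALSE))
  expect_equal(nofloor$se / fe$se, sqrt(q$q / q$q_df), tolerance = 1e-12)
})

test_that("Cochran's Q matches its chi-square closed form", {
  same <- make_set(c(1, 1, 1), c(0.3, 0.3, 0.3), se_y = 1)
  q0 <- cochran_q(same)
  expect_equal(q0$q, 0)
  expect_equal(q0$q_pvalue, 1)
  # two instruments, unit ratio SEs, ratios 0 and 2
  two <- make_set(c(1, 1), c(0, 2), se_y = 1)
  q <- cochran_q(two)
  expect_equal(q$q, 2)
  expect_equal(q$q_df, 1)
  expect_equal(q$q_pvalue, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(round(q$q_pvalue, 4), 0.1573)
  expect_true(is.na(cochran_q(make_set(1, 0.3))$q))
})

test_that("Q is chi-square distributed under homogeneity", {
  L <- 6
  withr::with_seed(88, {
    qs <- replicate(2000, {
      bx <- runif(L, 0.1, 0.5)
      sy <- runif(L, 0.02, 0.08)
      by <- rnorm(L, 0.25 * bx, sy)   # exact ratio-level normality
      cochran_q(make_set(bx, by, se_x = 1e-8, se_y = sy))$q
    })
  })
  ks <- ks.test(qs, pchisq, df = L - 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("weighted median interpolates the stated cumulative midpoints", {
  set <- make_set(c(1, 1, 1), c(0.1, 0.3, 0.9), se_y = 1)
  cfg <- estimator_config(seed = 5, bootstrap_iterations = 200)
  r <- weighted_median(set, cfg)
  expect_equal(r$beta, 0.3)
  # estimate bounded by the ratio range for random sets
  for (i in 1:10) {
    s <- random_set(7, seed = 300 + i)
    th <- s$pairs$beta_y / s$pairs$beta_x
    b <- weighted_median(s, cfg)$beta
    expect_gte(b, min(th)); expect_lte(b, max(th))
  }
  # equal weights, odd L, knot landing: the plain median
  odd <- make_set(rep(1, 5), c(0.5, 0.1, 0.4, 0.2, 0.3), se_y = 1)
  expect_equal(weighted_median(odd, cfg)$beta, 0.3)
  # determinism: identical seed, identical SE
  expect_identical(weighted_median(set, cfg)$se,
                   weighted_median(set, cfg)$se)
  expect_null(suppressMessages(weighted_median(make_set(1, 1), cfg)))
  expect_error(weighted_median(set, estimator_config()), "seed")
})

test_that("weighted mode finds the majority cluster", {
  cfg <- estimator_config(seed = 9, bootstrap_iterations = 200)
  flat <- make_set(rep(1, 4), rep(0.25, 4), se_y = 1)
  expect_equal(weighted_mode(flat, cfg)$beta, 0.25)
  clust <- make_set(rep(1, 5), c(0.28, 0.30, 0.31, 0.29, 3.0),
                    se_y = c(0.1, 0.1, 0.1, 0.1, 0.2))
  est <- weighted_mode(clust, cfg)$beta
  expect_gt(est, 0.2); expect_lt(est, 0.4)
  # KDE argmax oracle on the same fixture
  th <- clust$pairs$beta_y / clust$pairs$beta_x
  w <- clust$pairs$beta_x^2 / clust$pairs$se_y^2
  h <- 0.9 * min(sd(th), IQR(th) / 1.34) * 5^(-1 / 5)
  grid <- seq(min(th) - 3 * h, max(th) + 3 * h, length.out = 20000)
  dens <- vapply(grid, function(g)
    sum(w / sum(w) * dnorm((g - th) / h)), numeric(1))
  expect_equal(est, grid[which.max(dens)], tolerance = 0.01)
  expect_identical(weighted_mode(clust, cfg)$beta,
                   weighted_mode(clust, cfg)$beta)
})

test_that("MR-PRESSO flags a gross outlier and not clean sets", {
  cfg <- estimator_config(seed = 17, presso_simulations = 500)
  # clean, proportional sets across a batch of seeds
  clean_ok <- vapply(1:20, function(s) {
    set <- random_set(8, seed = 5000 + s)
    pr <- mr_presso(set, estimator_config(seed = s,
                                          presso_simulations = 300))
    pr$presso_global_p >= 0.05 && length(pr$presso_outliers) == 0
  }, logical(1))
  expect_gte(mean(clean_ok), 0.9)
  # one instrument whose ratio is 10x the rest
  withr::with_seed(1, {
    bx <- runif(10, 0.25, 0.35)
    by <- 0.3 * bx + rnorm(10, 0, 0.05)
  })
  by[10] <- 3 * bx[10]
  out <- make_set(bx, by, se_y = 0.05)
  pr <- mr_presso(out, cfg)
  expect_true("rs010" %in% pr$presso_outliers)
  expect_lt(pr$presso_global_p, 0.05)
  expect_lt(pr$corrected$n_snp, 10L)
  expect_lt(abs(pr$corrected$beta - 0.3), 0.15)
  # determinism
  expect_identical(mr_presso(out, cfg), mr_presso(out, cfg))
  expect_null(suppressMessages(mr_presso(make_set(c(1, 1, 1),
                                                  c(1, 1, 1)), cfg)))
})

test_that("odds-ratio conversion round-trips the standard error", {
  o <- to_odds_ratio(0, 0.1)
  expect_equal(o$or_point, 1)
  expect_equal(o$or_lcl, exp(-qnorm(0.975) * 0.1))
  withr::with_seed(10, {
    beta <- rnorm(50); se <- runif(50, 0.01, 0.5)
    o <- to_odds_ratio(beta, se)
    expect_equal(log(o$or_ucl / o$or_lcl) / (2 * qnorm(0.975)), se,
                 tolerance = 1e-10)
  })
})

test_that("estimates are invariant under joint per-variant sign flips", {
  set <- random_set(9, seed = 14)
  flipped <- set
  withr::with_seed(15, idx <- sample(9, 4))
  flipped$pairs$beta_x[idx] <- -flipped$pairs$beta_x[idx]
  flipped$pairs$beta_y[idx] <- -flipped$pairs$beta_y[idx]
  cfg <- estimator_config(seed = 3, bootstrap_iterations = 200)
  expect_equal(ivw(flipped, "mre")$beta, ivw(set, "mre")$beta,
               tolerance = 1e-12)
  expect_equal(ivw(flipped, "fe")$se, ivw(set, "fe")$se,
               tolerance = 1e-12)
  eg1 <- mr_egger(set); eg2 <- mr_egger(flipped)
  expect_equal(eg2$result$beta, eg1$result$beta, tolerance = 1e-12)
  expect_equal(eg2$egger_intercept, eg1$egger_intercept,
               tolerance = 1e-12)
  expect_equal(weighted_median(flipped, cfg)$beta,
               weighted_median(set, cfg)$beta, tolerance = 1e-12)
  expect_equal(weighted_mode(flipped, cfg)$beta,
               weighted_mode(set, cfg)$beta, tolerance = 1e-9)
})

test_that("mr_fit assembles the suite with working S3 methods", {
  set <- random_set(6, seed = 77)
  fit <- mr_fit(set, estimator_config(seed = 2,
                                      bootstrap_iterations = 200,
                                      presso_simulations = 200))
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$results$method,
                  c("ivw_mre", "ivw_fe", "egger", "weighted_median",
                    "weighted_mode"))
  expect_true(all(fit$results$lcl <= fit$results$or &
                    fit$results$or <= fit$results$ucl))
  expect_named(coef(fit), fit$results$method)
  ci <- confint(fit)
  expect_equal(unname(ci[, 2] - ci[, 1]),
               2 * qnorm(0.975) * fit$results$se)
  expect_output(print(fit), "ivw_mre")
  expect_output(print(summary(fit)), "Cochran Q")
  pr <- primary_result(fit)
  expect_equal(pr$method, "ivw_mre")
  # small sets skip the methods that need more instruments
  small <- mr_fit(make_set(0.3, 0.1), estimator_config(seed = 2))
  expect_setequal(small$skipped,
                  c("egger", "weighted_median", "weighted_mode", "presso"))
  expect_equal(small$results$method, c("wald", "ivw_mre", "ivw_fe"))
})
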