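# FDR control and the proteome-wide / phenome-wide drivers.

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  withr::with_seed(6, {
    for (i in 1:20) {
      p <- runif(sample(3:50, 1))
      expect_equal(bh_fdr(p), bh_oracle(p))
    }
  })
  # monotone: larger p never maps to smaller q
  withr::with_seed(7, p <- runif(100))
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_true(all(q >= p))
  # missing values are excluded from the family
  p <- c(0.01, NA, 0.02, 0.03)
  expect_equal(bh_fdr(p), c(bh_oracle(c(0.01, 0.02, 0.03))[1], NA,
                            bh_oracle(c(0.01, 0.02, 0.03))[2:3]))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("run_protein reports the full method suite on a known effect", {
  st <- simulate_study(simulation_config(theta = log(1.40), seed = 42))
  cfg <- estimator_config(seed = 9, bootstrap_iterations = 200,
                          presso_simulations = 200)
  row <- run_protein(st$exposures[[1]], st$genes[1, ], st$outcome,
                     st$ld, est_cfg = cfg)
  expect_equal(row$status, "ok")
  expect_true(all(c("ivw_mre", "ivw_fe", "egger", "weighted_median",
                    "weighted_mode") %in% row$fit$results$method))
  expect_equal(row$primary$method, "ivw_mre")
  # same seed, byte-identical repeat
  row2 <- run_protein(st$exposures[[1]], st$genes[1, ], st$outcome,
                      st$ld, est_cfg = cfg)
  expect_identical(row$fit$results, row2$fit$results)
})

test_that("a protein without significant variants reports no_instruments", {
  st <- simulate_study(simulation_config(seed = 5))
  ex <- st$exposures[[1]]
  ex$records$pval <- rep(0.5, nrow(ex$records))
  row <- run_protein(ex, st$genes[1, ], st$outcome, st$ld)
  expect_equal(row$status, "no_instruments")
  expect_null(row$fit)
})

test_that("strong signals survive proteome-wide FDR control", {
  hits <- vapply(1:10, function(s) {
    st <- simulate_study(simulation_config(
      n_proteins = 105, theta = c(rep(0, 100), rep(0.4, 5)),
      block_size = 1, n_null_variants = 2, decoy_fraction_mhc = 0,
      instrument_strength = c(5, 9), seed = 100 + s))
    scr <- run_proteome(st$exposures, st$genes, st$outcome, st$ld,
                        methods = "ivw_mre")
    sig <- sprintf("PROT%04d", 101:105)
    sum(scr$results$p_fdr[scr$results$exposure_id %in% sig] < 0.05,
        na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.8)
})

test_that("null screens show the nominal false-positive count", {
  counts <- vapply(1:5, function(s) {
    st <- simulate_study(simulation_config(
      n_proteins = 200, theta = 0, block_size = 1, n_null_variants = 0,
      decoy_fraction_mhc = 0, seed = 400 + s))
    scr <- run_proteome(st$exposures, st$genes, st$outcome, st$ld,
                        methods = "ivw_fe")
    scr$summary$n_nominal
  }, numeric(1))
  # 1000 pooled fixed-effect IVW tests at alpha = 0.05: binomial 99% band
  expect_gte(sum(counts), qbinom(0.005, 1000, 0.05))
  expect_lte(sum(counts), qbinom(0.995, 1000, 0.05))
})

test_that("protein order does not change the screen", {
  st <- simulate_study(simulation_config(
    n_proteins = 12, theta = c(rep(0, 10), 0.4, 0.4), seed = 77,
    block_size = 1))
  scr1 <- run_proteome(st$exposures, st$genes, st$outcome, st$ld,
                       methods = "ivw_mre")
  perm <- rev(seq_along(st$exposures))
  scr2 <- run_proteome(st$exposures[perm], st$genes, st$outcome, st$ld,
                       methods = "ivw_mre")
  r1 <- scr1$results
  r2 <- scr2$results[match(r1$exposure_id, scr2$results$exposure_id), ]
  rownames(r2) <- NULL
  expect_equal(r2, r1)
  expect_error(run_proteome(list(), st$genes, st$outcome), "empty")
})

test_that("the screen writes a parseable JSON-lines run log", {
  st <- simulate_study(simulation_config(n_proteins = 3, seed = 9,
                                         block_size = 1))
  log <- withr::local_tempfile(fileext = ".jsonl")
  run_proteome(st$exposures, st$genes, st$outcome, st$ld,
               methods = "ivw_mre", log_path = log)
  lines <- readLines(log)
  expect_length(lines, 4L)   # config header + one line per protein
  parsed <- lapply(lines, jsonlite::fromJSON)
  expect_equal(parsed[[1]]$event, "config")
  expect_equal(parsed[[1]]$p_threshold, 5e-8)
  expect_equal(vapply(parsed[-1], `[[`, character(1), "id"),
               sprintf("PROT%04d", 1:3))
})

test_that("the phewas driver enforces the case-count filter", {
  st <- simulate_exposure(simulation_config(seed = 2, block_size = 1,
                                            n_null_variants = 0,
                                            decoy_fraction_mhc = 0))
  iv <- select_instruments(st$exposures[[1]], st$genes[1, ], st$ld)
  v <- st$truth$variants
  mk_out <- function(id, n_cases) {
    n_eff <- n_cases * 391037 / (n_cases + 391037)
    se <- 1 / sqrt(2 * v$maf * (1 - v$maf) * n_eff)
    withr::with_seed(match(id, c("D49", "D50", "D51")) + 10,
                     beta <- rnorm(nrow(v), 0, se))
    make_stats(v$variant_id, beta, se, chr = v$chr, pos = v$pos,
               ea = v$ea, oa = v$oa, eaf = v$eaf, trait_id = id,
               trait_type = "binary", n_cases = n_cases,
               n_controls = 391037)
  }
  ph <- run_phewas(iv, list(mk_out("D49", 49), mk_out("D50", 50),
                            mk_out("D51", 51)),
                   est_cfg = estimator_config(seed = 1))
  expect_equal(ph$excluded, "D49")
  expect_setequal(ph$results$outcome_id, c("D50", "D51"))
  expect_error(
    run_phewas(iv, list(mk_out("D50", 60), mk_out("D50", 60))),
    "duplicate")
})

test_that("null phewas screens rarely produce FDR discoveries", {
  st <- simulate_exposure(simulation_config(seed = 3, block_size = 1,
                                            n_null_variants = 0,
                                            decoy_fraction_mhc = 0))
  iv <- select_instruments(st$exposures[[1]], st$genes[1, ], st$ld)
  clean <- vapply(1:30, function(s) {
    cfg <- simulation_config(seed = 700 + s, block_size = 1,
                             n_null_variants = 0,
                             decoy_fraction_mhc = 0)
    outs <- simulate_phewas_outcomes(st$truth, cfg, n_outcomes = 100,
                                     case_count_range = c(60, 2000))
    ph <- run_phewas(iv, outs, est_cfg = estimator_config(seed = s))
    ok <- ph$results$status == "ok"
    !any(ph$results$p_fdr[ok] < 0.05)
  }, logical(1))
  # under the global null BH rejects anything with probability alpha;
  # allow the binomial 99% margin around 95% clean seeds
  expect_gte(sum(clean), 30 - qbinom(0.99, 30, 0.05) - 1)
})
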