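# Fixture builders shared across the suite. Everything is generated in
# code; no stored data.

# A summary_stats object from parallel vectors with sensible defaults.
make_stats <- function(variant_id, beta, se, pval = NULL,
                       chr = "1", pos = NULL, ea = "A", oa = "G",
                       eaf = 0.3, n = 10000, trait_id = "trait",
                       trait_type = "quantitative",
                       n_cases = NA_integer_, n_controls = NA_integer_) {
  k <- length(variant_id)
  if (is.null(pos)) pos <- seq_len(k) * 1000
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)),
                                  .Machine$double.xmin)
  rec <- data.frame(variant_id = variant_id,
                    chr = rep_len(chr, k), pos = pos,
                    ea = rep_len(ea, k), oa = rep_len(oa, k),
                    eaf = rep_len(eaf, k), beta = beta, se = se,
                    pval = pval, n = rep_len(n, k),
                    stringsAsFactors = FALSE)
  summary_stats(trait_id, rec, trait_type = trait_type,
                n_cases = n_cases, n_controls = n_controls)
}

# A harmonized instrument set straight from effect vectors.
make_set <- function(beta_x, beta_y, se_x = 0.02, se_y = 0.05,
                     ids = NULL) {
  L <- length(beta_x)
  if (is.null(ids)) ids <- sprintf("rs%03d", seq_len(L))
  instrument_set("X", "Y", data.frame(
    variant_id = ids, beta_x = beta_x, se_x = rep_len(se_x, L),
    beta_y = beta_y, se_y = rep_len(se_y, L), stringsAsFactors = FALSE))
}

# Random instrument set used by the algebraic-oracle checks.
random_set <- function(L, seed) {
  withr::with_seed(seed, {
    beta_x <- runif(L, 0.05, 0.5) * sample(c(-1, 1), L, replace = TRUE)
    se_y <- runif(L, 0.01, 0.1)
    beta_y <- 0.3 * beta_x + rnorm(L, 0, se_y)
    make_set(beta_x, beta_y, se_x = runif(L, 0.005, 0.03), se_y = se_y)
  })
}

# Independent step-up BH oracle (deliberately naive): q_(i) =
# min_{k>=i} m p_(k)/k, clipped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Write a small sumstats TSV from a data frame of canonical columns.
write_tsv_fixture <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
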