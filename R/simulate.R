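# Seeded synthetic summary-statistics generator with known ground truth.
#
# Effects live on the standardized-genotype scale, so SEs take the closed
# form (2 * maf * (1 - maf) * n)^(-1/2); binary outcomes use the effective
# sample size n_cases * n_controls / (n_cases + n_controls), which carries
# the log-odds score variance. LD is simulated at the z-score level
# (exchangeable within-block correlation), sufficient to exercise clumping
# without individual-level genotypes.

#' Simulation configuration
#'
#' Defines the synthetic study: per-protein cis instruments with
#' genome-wide-significant exposure effects, a binary outcome on the
#' log-odds scale, optional pleiotropy, LD-correlated variant blocks, MHC
#' decoy variants and null cis variants. The default study dimensions
#' mirror a large plasma-proteome exposure panel (35,559 individuals) and
#' a rare binary outcome (1,543 cases / 391,037 controls), with 5
#' instruments per protein.
#'
#' @param n_proteins Number of protein exposures.
#' @param instruments_per_protein Causal cis variants (LD-block leads) per
#'   protein.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome case/control counts.
#' @param theta True causal log-odds effect per SD of protein level; scalar
#'   or length `n_proteins` (0 = null protein).
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct
#'   effects) or `"directional"` (mean `mu`).
#' @param tau SD of per-variant pleiotropic effects.
#' @param mu Mean pleiotropic effect (directional mode).
#' @param maf_range Uniform range for minor-allele frequencies.
#' @param block_size Variants per LD block (1 = no satellites).
#' @param block_r2 Within-block squared correlation.
#' @param n_null_variants Non-causal cis variants per protein.
#' @param decoy_fraction_mhc Fraction (of the protein's cis variant count)
#'   of significant decoy variants placed inside the MHC region on
#'   chromosome 6.
#' @param instrument_strength Multiplier range (length 2) on the
#'   genome-wide-significance effect size for the true lead effects; the
#'   lower bound keeps detection essentially certain at `n_exposure`.
#' @param allele_swap_rate Probability that an outcome record reports the
#'   alleles in the opposite order (beta negated accordingly) — a pure
#'   representation change that harmonization must undo.
#' @param strand_flip_rate Probability that an outcome record is written on
#'   the complementary strand.
#' @param missing_outcome_rate Probability that a variant is absent from
#'   the outcome table.
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 1, instruments_per_protein = 5,
                              n_exposure = 35559, n_cases = 1543,
                              n_controls = 391037, theta = 0,
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional"),
                              tau = 0, mu = 0, maf_range = c(0.05, 0.5),
                              block_size = 3, block_r2 = 0.8,
                              n_null_variants = 10,
                              decoy_fraction_mhc = 0.1,
                              instrument_strength = c(1.6, 3),
                              allele_swap_rate = 0.5,
                              strand_flip_rate = 0,
                              missing_outcome_rate = 0, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_proteins >= 1, instruments_per_protein >= 1,
            n_exposure >= 2, n_cases >= 2, n_controls >= 2, tau >= 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], block_size >= 1,
            block_r2 >= 0, block_r2 < 1, n_null_variants >= 0,
            decoy_fraction_mhc >= 0, instrument_strength[1] >= 1)
  theta <- rep_len(theta, n_proteins)
  structure(list(n_proteins = n_proteins,
                 instruments_per_protein = instruments_per_protein,
                 n_exposure = n_exposure, n_cases = n_cases,
                 n_controls = n_controls, theta = theta,
                 pleiotropy_mode = pleiotropy_mode, tau = tau, mu = mu,
                 maf_range = maf_range, block_size = block_size,
                 block_r2 = block_r2, n_null_variants = n_null_variants,
                 decoy_fraction_mhc = decoy_fraction_mhc,
                 instrument_strength = instrument_strength,
                 allele_swap_rate = allele_swap_rate,
                 strand_flip_rate = strand_flip_rate,
                 missing_outcome_rate = missing_outcome_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.Z_GWS <- function(p = 5e-8) stats::qnorm(1 - p / 2)

.ALLELE_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("A", "T"), c("C", "A"), c("C", "G"),
  c("C", "T"), c("G", "A"), c("G", "C"), c("G", "T"), c("T", "A"),
  c("T", "C"), c("T", "G"))

.se_closed_form <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

#' Simulate per-protein exposure summary statistics
#'
#' For each protein: a gene interval, `instruments_per_protein` LD-block
#' leads inside the cis window whose true standardized effects exceed
#' genome-wide significance at `n_exposure` by the configured strength
#' margin, correlated satellite variants per block, independent null cis
#' variants, and significant MHC decoy variants on chromosome 6. Observed
#' effects are the true effects plus correlated standard-normal z-score
#' noise (exchangeable correlation `sqrt(block_r2)` within a block).
#' Per-variant pleiotropic effects `alpha` are drawn here (per
#' `pleiotropy_mode`) and recorded in the truth table for
#' [simulate_outcome()].
#'
#' Genes cycle over chromosomes 1–22; the chromosome-6 gene is placed just
#' distal to the MHC so that its decoys fall inside the cis window and only
#' the MHC exclusion removes them.
#'
#' @param cfg A [simulation_config()].
#' @return List with `exposures` (list of `summary_stats`, one per
#'   protein), `genes` (annotation data frame), `ld` (an [ld_matrix()]
#'   over all variants), and `truth` (a `simulation_truth` list holding
#'   `proteins` (gene_id, theta), `variants` (true effects, alpha, maf,
#'   block), and the seed).
#' @export
simulate_exposure <- function(cfg = simulation_config()) {
  withr::with_seed(cfg$seed, .simulate_exposure_impl(cfg))
}

.simulate_exposure_impl <- function(cfg) {
  z_min <- .Z_GWS()
  chroms <- as.character(1:22)
  exposures <- vector("list", cfg$n_proteins)
  genes <- vector("list", cfg$n_proteins)
  truth_var <- vector("list", cfg$n_proteins)
  ld_ids <- character()
  ld_blocks <- list()

  for (i in seq_len(cfg$n_proteins)) {
    gene_id <- sprintf("PROT%04d", i)
    chr <- chroms[(i - 1L) %% 22L + 1L]
    g_start <- if (chr == "6") 33600000 else
      round(stats::runif(1, 5e6, 2e8))
    g_end <- g_start + round(stats::runif(1, 5e3, 5e4))

    L <- cfg$instruments_per_protein
    bs <- cfg$block_size
    r <- sqrt(cfg$block_r2)
    n_cis <- L * bs + cfg$n_null_variants
    n_mhc <- ceiling(cfg$decoy_fraction_mhc * n_cis)

    # lead + satellite layout
    block <- c(rep(seq_len(L), each = bs),
               rep(NA_integer_, cfg$n_null_variants),
               rep(-seq_len(n_mhc)))                 # negative = MHC decoy
    is_lead <- c(rep(c(TRUE, rep(FALSE, bs - 1L)), L),
                 rep(FALSE, cfg$n_null_variants), rep(TRUE, n_mhc))
    nv <- length(block)
    vid <- sprintf("rs%d_%03d", i, seq_len(nv))

    maf <- stats::runif(nv, cfg$maf_range[1], cfg$maf_range[2])
    se_x <- .se_closed_form(maf, cfg$n_exposure)

    # positions: block leads spread over the cis window, satellites close
    # by, nulls anywhere in the window, decoys inside the MHC
    lead_pos <- round(seq(g_start - 0.9e6, g_end + 0.9e6,
                          length.out = L))
    pos <- numeric(nv)
    chr_v <- rep(chr, nv)
    for (b in seq_len(L)) {
      idx <- which(block == b & !is.na(block))
      pos[idx] <- lead_pos[b] + c(0, round(stats::runif(bs - 1L, 1, 5e4)))
    }
    nulls <- which(is.na(block))
    pos[nulls] <- round(stats::runif(length(nulls), g_start - 1e6,
                                     g_end + 1e6))
    mhc <- which(!is.na(block) & block < 0)
    pos[mhc] <- round(stats::runif(length(mhc), 28477897, 33448354))
    chr_v[mhc] <- "6"
    pos <- pmax(pos, 1)

    # true standardized effects: leads exceed genome-wide significance by
    # the configured margin; satellites attenuate by r on the z scale
    z_true <- numeric(nv)
    sgn <- sample(c(-1, 1), L + length(mhc), replace = TRUE)
    mult <- stats::runif(L + length(mhc), cfg$instrument_strength[1],
                         cfg$instrument_strength[2])
    lead_idx <- which(is_lead)
    z_true[lead_idx] <- sgn * mult * z_min
    for (b in seq_len(L)) {
      idx <- which(block == b & !is.na(block))
      z_true[idx[-1]] <- r * z_true[idx[1]]
    }

    # correlated z-score noise within blocks (exchangeable corr r)
    z_obs <- numeric(nv)
    for (b in unique(block[!is.na(block) & block > 0])) {
      idx <- which(!is.na(block) & block == b)
      k <- length(idx)
      shared <- stats::rnorm(1)
      own <- stats::rnorm(k)
      # exchangeable corr r between any pair of z-scores in the block
      z_obs[idx] <- z_true[idx] + sqrt(r) * shared + sqrt(1 - r) * own
    }
    rest <- which(is.na(block) | block < 0)
    z_obs[rest] <- z_true[rest] + stats::rnorm(length(rest))

    beta_true <- z_true * se_x
    beta_obs <- z_obs * se_x
    pval <- 2 * stats::pnorm(-abs(z_obs))
    pval <- pmax(pval, .Machine$double.xmin)

    ap <- .ALLELE_PAIRS[sample.int(nrow(.ALLELE_PAIRS), nv,
                                   replace = TRUE), , drop = FALSE]
    eaf <- ifelse(stats::runif(nv) < 0.5, maf, 1 - maf)

    # directional pleiotropy is defined per exposure-increasing allele:
    # orient the drawn effect by the sign of the true exposure effect,
    # otherwise random allele coding would cancel the direction
    alpha <- switch(cfg$pleiotropy_mode,
                    none = numeric(nv),
                    balanced = stats::rnorm(nv, 0, cfg$tau),
                    directional = sign(z_true) *
                      stats::rnorm(nv, cfg$mu, cfg$tau))

    rec <- .df(variant_id = vid, chr = chr_v, pos = pos,
               ea = ap[, 1], oa = ap[, 2], eaf = eaf,
               beta = beta_obs, se = se_x, pval = pval,
               n = rep(cfg$n_exposure, nv))
    exposures[[i]] <- summary_stats(gene_id, rec)
    genes[[i]] <- .df(gene_id = gene_id, chr = chr, start = g_start,
                      end = g_end)
    truth_var[[i]] <- .df(
      gene_id = rep(gene_id, nv), variant_id = vid, chr = chr_v,
      pos = pos, ea = ap[, 1], oa = ap[, 2], eaf = eaf, maf = maf,
      beta_x_true = beta_true, alpha = alpha, se_x = se_x,
      block = block, is_lead = is_lead)

    # LD entries: exchangeable r2 within positive blocks, decoys/nulls
    # independent
    for (b in seq_len(L)) {
      idx <- which(!is.na(block) & block == b)
      ld_blocks[[length(ld_blocks) + 1L]] <-
        .df(block_id = rep(sprintf("%s_b%d", gene_id, b), length(idx)),
            variant_id = vid[idx], r2 = rep(cfg$block_r2, length(idx)))
    }
    singletons <- vid[is.na(block) | block < 0]
    if (length(singletons))
      ld_blocks[[length(ld_blocks) + 1L]] <-
        .df(block_id = paste0(gene_id, "_s", seq_along(singletons)),
            variant_id = singletons,
            r2 = rep(0, length(singletons)))
    ld_ids <- c(ld_ids, vid)
  }

  ld <- ld_from_blocks(do.call(rbind, ld_blocks))
  truth <- structure(
    list(proteins = data.frame(gene_id = sprintf("PROT%04d",
                                                 seq_len(cfg$n_proteins)),
                               theta = cfg$theta,
                               stringsAsFactors = FALSE),
         variants = do.call(rbind, truth_var), seed = cfg$seed),
    class = "simulation_truth")
  list(exposures = exposures, genes = do.call(rbind, genes), ld = ld,
       truth = truth)
}

#' Simulate outcome summary statistics from a simulation truth
#'
#' The generating model of the estimators: per variant, the true outcome
#' effect is `theta * beta_x_true + alpha` on the log-odds scale; its SE is
#' the closed form at the effective sample size
#' `n_cases * n_controls / (n_cases + n_controls)`; the observed effect
#' adds normal noise. Allele representation is then optionally scrambled
#' (EA/OA swaps with beta negated and frequency complemented; strand
#' complements) at the configured rates — pure relabellings that
#' [harmonize()] must undo. Scrambling uses a separate RNG substream
#' (`seed + 2`) so a scrambled and a clean outcome from the same seed carry
#' identical underlying associations.
#'
#' @param truth A `simulation_truth` from [simulate_exposure()].
#' @param cfg The same [simulation_config()].
#' @return A binary-trait `summary_stats` covering all simulated variants.
#' @export
simulate_outcome <- function(truth, cfg) {
  v <- truth$variants
  theta <- truth$proteins$theta[match(v$gene_id, truth$proteins$gene_id)]
  n_eff <- cfg$n_cases * cfg$n_controls / (cfg$n_cases + cfg$n_controls)
  se_y <- .se_closed_form(v$maf, n_eff)
  beta_true <- theta * v$beta_x_true + v$alpha

  withr::with_seed(cfg$seed + 1L, {
    beta_obs <- stats::rnorm(nrow(v), beta_true, se_y)
    keep <- stats::runif(nrow(v)) >= cfg$missing_outcome_rate
  })
  pval <- pmax(2 * stats::pnorm(-abs(beta_obs / se_y)),
               .Machine$double.xmin)
  rec <- .df(variant_id = v$variant_id, chr = v$chr, pos = v$pos,
             ea = v$ea, oa = v$oa, eaf = v$eaf, beta = beta_obs,
             se = se_y, pval = pval,
             n = rep(cfg$n_cases + cfg$n_controls, nrow(v)))

  withr::with_seed(cfg$seed + 2L, {
    swap <- stats::runif(nrow(rec)) < cfg$allele_swap_rate
    flip <- stats::runif(nrow(rec)) < cfg$strand_flip_rate
  })
  rec <- .scramble_records(rec, swap, flip)
  rec <- rec[keep, , drop = FALSE]
  summary_stats("outcome", rec, trait_type = "binary",
                n_cases = cfg$n_cases, n_controls = cfg$n_controls)
}

# Apply allele-representation changes: swap = report the other allele as
# effect allele (beta negated, eaf complemented); flip = complementary
# strand labels (association unchanged).
.scramble_records <- function(rec, swap, flip) {
  ea <- rec$ea; oa <- rec$oa
  # a strand flip is representation-invariant only for non-palindromic
  # pairs; palindromes keep their reported strand
  flip <- flip & rec$ea != unname(.COMPLEMENT[rec$oa])
  rec$ea[swap] <- oa[swap]
  rec$oa[swap] <- ea[swap]
  rec$beta[swap] <- -rec$beta[swap]
  rec$eaf[swap] <- 1 - rec$eaf[swap]
  rec$ea[flip] <- unname(.COMPLEMENT[rec$ea[flip]])
  rec$oa[flip] <- unname(.COMPLEMENT[rec$oa[flip]])
  rec
}

#' Simulate a bank of PheWAS outcome traits
#'
#' Independent binary outcomes over the same variants, with case counts
#' drawn uniformly from `case_count_range` (spanning the PheWAS
#' case-count filter boundary). Outcomes are null unless a `theta_spike`
#' is supplied for some of them.
#'
#' @param truth A `simulation_truth`.
#' @param cfg A [simulation_config()].
#' @param n_outcomes Number of outcome traits.
#' @param case_count_range Integer range for per-outcome case counts.
#' @param theta_spike Optional numeric vector, length `n_outcomes`, of true
#'   causal effects (default all 0).
#' @return List of binary-trait `summary_stats`, ids `"D0001"`, ...
#' @export
simulate_phewas_outcomes <- function(truth, cfg, n_outcomes = 100,
                                     case_count_range = c(10, 500),
                                     theta_spike = NULL) {
  if (is.null(theta_spike)) theta_spike <- numeric(n_outcomes)
  stopifnot(length(theta_spike) == n_outcomes)
  v <- truth$variants
  withr::with_seed(cfg$seed + 3L, {
    lapply(seq_len(n_outcomes), function(k) {
      n_cases <- sample(seq(case_count_range[1], case_count_range[2]), 1)
      n_eff <- n_cases * cfg$n_controls / (n_cases + cfg$n_controls)
      se_y <- .se_closed_form(v$maf, n_eff)
      beta_true <- theta_spike[k] * v$beta_x_true
      beta_obs <- stats::rnorm(nrow(v), beta_true, se_y)
      rec <- data.frame(variant_id = v$variant_id, chr = v$chr,
                        pos = v$pos, ea = v$ea, oa = v$oa, eaf = v$eaf,
                        beta = beta_obs, se = se_y,
                        pval = pmax(2 * stats::pnorm(-abs(beta_obs / se_y)),
                                    .Machine$double.xmin),
                        n = n_cases + cfg$n_controls,
                        stringsAsFactors = FALSE)
      summary_stats(sprintf("D%04d", k), rec, trait_type = "binary",
                    n_cases = n_cases, n_controls = cfg$n_controls)
    })
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: [simulate_exposure()] then [simulate_outcome()].
#'
#' @param cfg A [simulation_config()].
#' @return List `exposures`, `genes`, `ld`, `truth`, `outcome`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  s <- simulate_exposure(cfg)
  s$outcome <- simulate_outcome(s$truth, cfg)
  s
}

#' Write a simulated study to a directory
#'
#' Emits `exposures/<protein>.tsv`, `outcome.tsv`, `genes.tsv`,
#' `ld_blocks.tsv` and `truth.tsv`, all readable back by the package's
#' readers.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "exposures"), recursive = TRUE,
             showWarnings = FALSE)
  for (ex in study$exposures)
    write_sumstats(ex, file.path(dir, "exposures",
                                 paste0(ex$trait_id, ".tsv")))
  write_sumstats(study$outcome, file.path(dir, "outcome.tsv"))
  write_gene_annotations(study$genes, file.path(dir, "genes.tsv"))
  r2m <- study$ld$r2
  idx <- which(upper.tri(r2m) & r2m > 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(id_i = study$ld$variant_ids[idx[, 1]],
               id_j = study$ld$variant_ids[idx[, 2]],
               r2 = r2m[idx]),
    file.path(dir, "ld_blocks.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(study$truth$variants, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
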