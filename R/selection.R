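# cis-pQTL instrument selection: genome-wide significance, MHC exclusion,
# cis-window filtering, greedy LD clumping, outcome-overlap exclusion and
# per-variant F statistics.

#' Instrument-selection configuration
#'
#' Thresholds for cis-pQTL instrument selection. Defaults follow the usual
#' proteome-MR practice: genome-wide significance p < 5e-8 (strict
#' inequality), a 1 Mb cis window around the gene body, exclusion of the
#' extended MHC region on chromosome 6 (28,477,897–33,448,354 bp), LD
#' clumping at r^2 = 0.001 within 10,000 kb, removal of instruments
#' associated with the outcome at p < 5e-8, and a weak-instrument screen at
#' F > 10.
#'
#' @param p_threshold Exposure significance cutoff (strict `<`).
#' @param cis_window Cis distance in bp from the gene start/end.
#' @param mhc_chromosome,mhc_start,mhc_end MHC region to exclude.
#' @param clump_r2 LD r-squared above which variants are clumped away.
#' @param clump_window Clumping distance in bp.
#' @param outcome_p_exclusion Outcome p-value below which an instrument is
#'   removed (strict `<`).
#' @param f_min Minimum per-variant F statistic (kept when F > `f_min`).
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_threshold = 5e-8, cis_window = 1e6,
                             mhc_chromosome = "6", mhc_start = 28477897,
                             mhc_end = 33448354, clump_r2 = 0.001,
                             clump_window = 1e7,
                             outcome_p_exclusion = 5e-8, f_min = 10) {
  stopifnot(p_threshold > 0, cis_window > 0, mhc_start > 0,
            mhc_end >= mhc_start, clump_r2 > 0, clump_r2 < 1,
            clump_window > 0, outcome_p_exclusion > 0, f_min > 0)
  structure(list(p_threshold = p_threshold, cis_window = cis_window,
                 mhc_chromosome = as.character(mhc_chromosome),
                 mhc_start = mhc_start, mhc_end = mhc_end,
                 clump_r2 = clump_r2, clump_window = clump_window,
                 outcome_p_exclusion = outcome_p_exclusion, f_min = f_min),
            class = "selection_config")
}

.subset_stats <- function(stats, keep) {
  stats$records <- .df_rows(stats$records, keep)
  stats
}

#' Keep genome-wide-significant associations
#'
#' Retains records with `pval` strictly below the significance threshold.
#'
#' @param stats A `summary_stats` object.
#' @param cfg A [selection_config()].
#' @return Filtered `summary_stats` (possibly empty).
#' @export
select_significant <- function(stats, cfg = selection_config()) {
  .subset_stats(stats, stats$records$pval < cfg$p_threshold)
}

#' Exclude the MHC region
#'
#' Drops records on the MHC chromosome with position inside
#' `[mhc_start, mhc_end]` (inclusive). The MHC is conventionally excluded
#' because its extreme long-range LD defeats clumping.
#'
#' @inheritParams select_significant
#' @return Filtered `summary_stats`.
#' @export
exclude_mhc <- function(stats, cfg = selection_config()) {
  r <- stats$records
  drop <- !is.na(r$chr) & r$chr == cfg$mhc_chromosome &
    !is.na(r$pos) & r$pos >= cfg$mhc_start & r$pos <= cfg$mhc_end
  .subset_stats(stats, !drop)
}

#' Keep cis variants around a gene
#'
#' Retains records on the gene's chromosome with position within
#' `cis_window` bp of the gene body, i.e. in
#' `[start - cis_window, end + cis_window]` inclusive.
#'
#' @inheritParams select_significant
#' @param gene One gene annotation: a list/row with `chr`, `start`, `end`.
#' @return Filtered `summary_stats`.
#' @export
filter_cis <- function(stats, gene, cfg = selection_config()) {
  r <- stats$records
  keep <- !is.na(r$chr) & r$chr == as.character(gene$chr) &
    !is.na(r$pos) & r$pos >= gene$start - cfg$cis_window &
    r$pos <= gene$end + cfg$cis_window
  .subset_stats(stats, keep)
}

#' Construct an LD matrix
#'
#' @param variant_ids Character vector of variant ids (order defines the
#'   matrix order).
#' @param r2 Square symmetric matrix of squared correlations in \[0, 1\]
#'   with unit diagonal.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(variant_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(length(variant_ids) == nrow(r2), nrow(r2) == ncol(r2))
  if (any(abs(r2 - t(r2)) > 1e-8)) stop("LD matrix is not symmetric")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) stop("LD r2 values outside [0, 1]")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r2 = r2),
            class = "ld_matrix")
}

#' Read an LD matrix from a pairwise TSV
#'
#' File of rows `id_i<TAB>id_j<TAB>r2`; unlisted pairs are taken as
#' uncorrelated (r2 = 0) and the diagonal as 1.
#'
#' @param path File path.
#' @param variant_ids Optional universe of ids; defaults to the ids seen.
#' @return An `ld_matrix`.
#' @export
read_ld_pairs <- function(path, variant_ids = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "numeric"))
  names(df) <- c("id_i", "id_j", "r2")
  if (is.null(variant_ids))
    variant_ids <- sort(unique(c(df$id_i, df$id_j)))
  m <- diag(1, length(variant_ids))
  dimnames(m) <- list(variant_ids, variant_ids)
  m[cbind(df$id_i, df$id_j)] <- df$r2
  m[cbind(df$id_j, df$id_i)] <- df$r2
  ld_matrix(variant_ids, m)
}

#' Build an LD matrix from a block specification
#'
#' All pairs within a block share a common r2; pairs across blocks are
#' uncorrelated.
#'
#' @param blocks Data frame with columns `block_id`, `variant_id`, `r2`
#'   (the within-block r2, constant per block).
#' @return An `ld_matrix`.
#' @export
ld_from_blocks <- function(blocks) {
  ids <- as.character(blocks$variant_id)
  stopifnot(!anyDuplicated(ids))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (idx in split(seq_len(n), blocks$block_id)) {
    if (length(idx) > 1L) m[idx, idx] <- blocks$r2[idx[1]]
  }
  diag(m) <- 1
  ld_matrix(ids, m)
}

#' Greedy LD clumping
#'
#' Thins correlated variants: records are ranked by p-value (ties broken by
#' variant id, lexicographically); the best-ranked variant is kept and every
#' remaining variant on the same chromosome within `clump_window` bp with
#' r2 strictly above `clump_r2` is removed; the process repeats on the
#' remainder. Variants absent from the LD matrix are treated as uncorrelated
#' and counted in the `clump_log` attribute.
#'
#' @inheritParams select_significant
#' @param ld An [ld_matrix()] covering (at least) the retained variants.
#' @return Filtered `summary_stats` of index variants; attribute
#'   `clump_log` records the number of variants missing from `ld`.
#' @export
ld_clump <- function(stats, ld, cfg = selection_config()) {
  stopifnot(inherits(ld, "ld_matrix"))
  r <- stats$records
  if (nrow(r) <= 1L) return(stats)
  ord <- order(r$pval, r$variant_id)
  r <- .df_rows(r, ord)
  in_ld <- r$variant_id %in% ld$variant_ids
  n_missing <- sum(!in_ld)
  idx_ld <- match(r$variant_id, ld$variant_ids)

  alive <- rep(TRUE, nrow(r))
  keep <- logical(nrow(r))
  for (i in seq_len(nrow(r))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive)
    if (!length(cand)) break
    same_chr <- !is.na(r$chr[cand]) & !is.na(r$chr[i]) &
      r$chr[cand] == r$chr[i]
    near <- same_chr & !is.na(r$pos[cand]) & !is.na(r$pos[i]) &
      abs(r$pos[cand] - r$pos[i]) <= cfg$clump_window
    linked <- rep(FALSE, length(cand))
    if (in_ld[i]) {
      has <- in_ld[cand]
      linked[has] <- ld$r2[idx_ld[i], idx_ld[cand][has]] > cfg$clump_r2
    }
    alive[cand[near & linked]] <- FALSE
  }
  stats <- .subset_stats(stats,
                         stats$records$variant_id %in% r$variant_id[keep])
  attr(stats, "clump_log") <- c(missing_from_ld = n_missing)
  stats
}

#' Remove instruments strongly associated with the outcome
#'
#' Drops instruments whose outcome p-value is strictly below
#' `outcome_p_exclusion` (to avoid instruments acting directly on the
#' outcome); instruments absent from the outcome table are also dropped and
#' counted.
#'
#' @param instruments `summary_stats` of selected instruments (exposure
#'   side).
#' @param outcome `summary_stats` for the outcome trait.
#' @param cfg A [selection_config()].
#' @return Filtered `summary_stats`; attribute `outcome_exclusion_log`
#'   counts drops by reason.
#' @export
exclude_outcome_associated <- function(instruments, outcome,
                                       cfg = selection_config()) {
  m <- match(instruments$records$variant_id, outcome$records$variant_id)
  missing <- is.na(m)
  p_out <- outcome$records$pval[m]
  assoc <- !missing & p_out < cfg$outcome_p_exclusion
  out <- .subset_stats(instruments, !missing & !assoc)
  attr(out, "outcome_exclusion_log") <-
    c(missing_in_outcome = sum(missing),
      outcome_associated = sum(assoc, na.rm = TRUE))
  out
}

#' Per-variant F statistic
#'
#' The squared z-ratio `(beta/se)^2`, used as the weak-instrument screen
#' (instruments with F at or below `f_min` are discarded in
#' [select_instruments()]).
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Numeric vector of F values.
#' @export
f_statistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) stop("se must be > 0")
  (beta / se)^2
}

#' Select cis-pQTL instruments for one protein
#'
#' Composition of the selection steps in order: genome-wide significance,
#' MHC exclusion, cis-window filter, LD clumping, F-statistic screen.
#' (Outcome-overlap exclusion is applied separately, after matching against
#' the outcome — see [exclude_outcome_associated()].) Per-step kept counts
#' are recorded in the `selection_log` attribute.
#'
#' @param exposure `summary_stats` for the protein.
#' @param gene Gene annotation row (`chr`, `start`, `end`).
#' @param ld An [ld_matrix()], or `NULL` to skip clumping (all variants
#'   treated as independent).
#' @param cfg A [selection_config()].
#' @return `summary_stats` of instruments with a `selection_log` attribute.
#' @export
select_instruments <- function(exposure, gene, ld = NULL,
                               cfg = selection_config()) {
  log <- c(input = nrow(exposure$records))
  s <- select_significant(exposure, cfg)
  log["significant"] <- nrow(s$records)
  s <- exclude_mhc(s, cfg)
  log["after_mhc"] <- nrow(s$records)
  s <- filter_cis(s, gene, cfg)
  log["cis"] <- nrow(s$records)
  if (!is.null(ld)) s <- ld_clump(s, ld, cfg)
  log["clumped"] <- nrow(s$records)
  keep <- f_statistic(s$records$beta, s$records$se) > cfg$f_min
  s <- .subset_stats(s, keep)
  log["strong"] <- nrow(s$records)
  attr(s, "selection_log") <- log
  s
}
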