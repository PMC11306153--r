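# Exposure/outcome allele harmonization: align both effect estimates to the
# same effect allele per variant before any MR fit.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonization configuration
#'
#' @param palindromic_eaf_tolerance Half-width of the allele-frequency
#'   ambiguity zone around 0.5 inside which a palindromic (A/T or C/G)
#'   variant cannot be oriented and is dropped. The default 0.08 drops
#'   palindromes with frequency in (0.42, 0.58), the common two-sample MR
#'   practice.
#' @param allow_strand_flip Resolve complementary-strand allele codings for
#'   non-palindromic variants instead of dropping them.
#' @return A `harmonization_config` list.
#' @export
harmonization_config <- function(palindromic_eaf_tolerance = 0.08,
                                 allow_strand_flip = TRUE) {
  stopifnot(palindromic_eaf_tolerance >= 0, palindromic_eaf_tolerance < 0.5)
  structure(list(palindromic_eaf_tolerance = palindromic_eaf_tolerance,
                 allow_strand_flip = allow_strand_flip),
            class = "harmonization_config")
}

#' Construct an instrument set
#'
#' The harmonized per-variant exposure/outcome effect pairs entering one MR
#' analysis.
#'
#' @param exposure_id,outcome_id Trait identifiers.
#' @param pairs Data frame with columns `variant_id`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y`, `eaf_x`, `eaf_y`, `p_x`, `p_y`.
#' @param log Data frame (`variant_id`, `action`) recording the
#'   harmonization decision per input variant.
#' @return An `instrument_set` object.
#' @export
instrument_set <- function(exposure_id, outcome_id, pairs,
                           log = NULL) {
  need <- c("variant_id", "beta_x", "se_x", "beta_y", "se_y",
            "eaf_x", "eaf_y", "p_x", "p_y")
  for (col in setdiff(need, names(pairs)))
    pairs[[col]] <- rep(NA_real_, nrow(pairs))
  pairs <- pairs[need]
  stopifnot(all(pairs$se_x > 0), all(pairs$se_y > 0),
            !anyDuplicated(pairs$variant_id))
  rownames(pairs) <- NULL
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 pairs = pairs, log = log),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s -> %s: %d instruments\n",
              x$exposure_id, x$outcome_id, nrow(x$pairs)))
  if (!is.null(x$log)) {
    tab <- table(x$log$action)
    cat("  harmonization:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of instruments in a set
#' @param set An `instrument_set`.
#' @return Integer count.
#' @export
n_instruments <- function(set) nrow(set$pairs)

.is_palindromic <- function(ea, oa) ea == .COMPLEMENT[oa]

#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants by id and aligns the outcome effect to the exposure's
#' effect allele. Per matched variant: identical allele pairs are kept as
#' is; swapped pairs (EA and OA exchanged) flip the sign of the outcome
#' beta and complement its frequency; complementary-strand codings are
#' resolved to one of those two cases when `allow_strand_flip` is on.
#' Palindromic variants (A/T or C/G), whose strand cannot be inferred from
#' the alleles, are kept only when both allele frequencies are present,
#' both lie outside the ambiguity zone around 0.5, and both fall on the
#' same side of 0.5 after alignment; otherwise they are dropped. Any other
#' allele configuration is dropped as incompatible, and exposure variants
#' missing from the outcome are dropped as missing. Every decision is
#' recorded per variant in the returned log.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param cfg A [harmonization_config()].
#' @return An [instrument_set()] with a per-variant `log` of actions from
#'   `{kept, sign_flipped, strand_flipped, dropped_palindromic,
#'   dropped_incompatible, dropped_missing}`.
#' @export
harmonize <- function(exposure, outcome, cfg = harmonization_config()) {
  ex <- exposure$records
  m <- match(ex$variant_id, outcome$records$variant_id)
  action <- rep(NA_character_, nrow(ex))
  action[is.na(m)] <- "dropped_missing"
  matched <- which(!is.na(m))
  oy <- .df_rows(outcome$records, m[matched])
  exm <- .df_rows(ex, matched)

  ea_x <- exm$ea; oa_x <- exm$oa
  ea_y <- oy$ea;  oa_y <- oy$oa
  pal <- .is_palindromic(ea_x, oa_x)
  ident <- ea_y == ea_x & oa_y == oa_x
  swap  <- ea_y == oa_x & oa_y == ea_x
  cea <- unname(.COMPLEMENT[ea_y]); coa <- unname(.COMPLEMENT[oa_y])
  s_ident <- cea == ea_x & coa == oa_x
  s_swap  <- cea == oa_x & coa == ea_x

  flip <- rep(NA, length(matched))     # negate outcome beta?
  act <- rep("dropped_incompatible", length(matched))

  # palindromic: labels identical/swapped is all the alleles can say;
  # orientation confirmed (or refuted) by the frequencies below
  p_keep <- pal & ident
  p_flip <- pal & swap
  flip[p_keep] <- FALSE
  flip[p_flip] <- TRUE
  act[p_keep | p_flip] <- "palindromic"

  np <- !pal
  flip[np & ident] <- FALSE; act[np & ident] <- "kept"
  flip[np & swap]  <- TRUE;  act[np & swap]  <- "sign_flipped"
  if (cfg$allow_strand_flip) {
    st_i <- np & !ident & !swap & s_ident
    st_s <- np & !ident & !swap & s_swap
    flip[st_i] <- FALSE
    flip[st_s] <- TRUE
    act[st_i | st_s] <- "strand_flipped"
  }

  beta_y <- ifelse(flip, -oy$beta, oy$beta)
  eaf_y  <- ifelse(flip, 1 - oy$eaf, oy$eaf)

  # resolve palindromes on frequency: both present, both outside the
  # ambiguity zone, same side of 0.5 after alignment
  is_p <- act == "palindromic"
  if (any(is_p)) {
    lo <- 0.5 - cfg$palindromic_eaf_tolerance
    hi <- 0.5 + cfg$palindromic_eaf_tolerance
    fx <- exm$eaf[is_p]; fy <- eaf_y[is_p]
    ok <- !is.na(fx) & !is.na(fy) &
      (fx <= lo | fx >= hi) & (fy <= lo | fy >= hi) &
      ((fx < 0.5) == (fy < 0.5))
    act[is_p] <- ifelse(ok,
                        ifelse(flip[is_p], "sign_flipped", "kept"),
                        "dropped_palindromic")
  }

  action[matched] <- act
  keep <- act %in% c("kept", "sign_flipped", "strand_flipped")
  pairs <- .df(
    variant_id = exm$variant_id[keep],
    beta_x = exm$beta[keep], se_x = exm$se[keep],
    beta_y = beta_y[keep], se_y = oy$se[keep],
    eaf_x = exm$eaf[keep], eaf_y = eaf_y[keep],
    p_x = exm$pval[keep], p_y = oy$pval[keep])
  instrument_set(exposure$trait_id, outcome$trait_id, pairs,
                 log = .df(variant_id = ex$variant_id, action = action))
}

#' Orient all exposure effects positive
#'
#' Jointly negates (`beta_x`, `beta_y`) for every pair with a negative
#' exposure effect. Wald ratios, IVW and median/mode estimates are invariant
#' under this relabelling; the MR-Egger intercept is not, which is why the
#' Egger fit applies it internally.
#'
#' @param set An `instrument_set`.
#' @return The re-oriented `instrument_set`.
#' @export
orient_positive_exposure <- function(set) {
  neg <- set$pairs$beta_x < 0
  set$pairs$beta_x[neg] <- -set$pairs$beta_x[neg]
  set$pairs$beta_y[neg] <- -set$pairs$beta_y[neg]
  if (!is.na(match("eaf_x", names(set$pairs)))) {
    set$pairs$eaf_x[neg] <- 1 - set$pairs$eaf_x[neg]
    set$pairs$eaf_y[neg] <- 1 - set$pairs$eaf_y[neg]
  }
  set
}

#' Write the harmonization log as TSV
#'
#' @param set An `instrument_set` produced by [harmonize()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_harmonization_log <- function(set, path) {
  stopifnot(!is.null(set$log))
  utils::write.table(set$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
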