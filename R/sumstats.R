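# GWAS summary-statistics data model and delimited-text I/O.
#
# Coordinates are 1-based inclusive throughout the package (the usual GWAS
# summary-statistics convention); BED input is converted on read.

#' Canonical summary-statistics column order
#'
#' Internal constant: the canonical record columns, in the order written by
#' [write_sumstats()].
#' @noRd
.SUMSTAT_COLS <- c("variant_id", "chr", "pos", "ea", "oa", "eaf",
                   "beta", "se", "pval", "n")

#' Default column-name mapping for summary-statistics tables
#'
#' Maps canonical field names to the column names expected in an input file.
#' Override individual entries to read files with other headers, e.g.
#' `sumstats_dialect(pval = "p_value")`.
#'
#' @param variant_id,chr,pos,ea,oa,eaf,beta,se,pval,n Column names in the
#'   input file for, respectively: variant identifier, chromosome, base-pair
#'   position (1-based), effect allele, other allele, effect-allele
#'   frequency, per-allele effect, its standard error, p-value, sample size.
#' @return Named list of column names.
#' @export
sumstats_dialect <- function(variant_id = "variant_id", chr = "chr",
                             pos = "pos", ea = "ea", oa = "oa", eaf = "eaf",
                             beta = "beta", se = "se", pval = "pval",
                             n = "n") {
  list(variant_id = variant_id, chr = chr, pos = pos, ea = ea, oa = oa,
       eaf = eaf, beta = beta, se = se, pval = pval, n = n)
}

#' Construct a summary-statistics object
#'
#' The container for one trait's GWAS summary associations: a validated
#' variant-level table plus trait metadata. Records violating the
#' variant-association invariants (identical or non-ACGT alleles,
#' non-positive SE, p-value outside (0, 1], frequency outside \[0, 1\],
#' position below 1, duplicated variant id) are dropped and counted, so no
#' downstream operation ever sees an invalid record. Indels (multi-base
#' alleles) are dropped: harmonization is defined for single-nucleotide
#' variants only.
#'
#' @param trait_id Character scalar naming the trait.
#' @param records Data frame with columns `variant_id`, `chr`, `pos`, `ea`,
#'   `oa`, `eaf`, `beta`, `se`, `pval`, `n` (missing optional columns
#'   `eaf`/`n`/`chr`/`pos` are filled with `NA`).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_cases,n_controls Case/control counts (binary traits).
#' @return An object of class `summary_stats`: a list with elements
#'   `trait_id`, `trait_type`, `n_cases`, `n_controls`, `records` and a
#'   `drop_log` attribute counting records removed per reason.
#' @export
summary_stats <- function(trait_id, records,
                          trait_type = c("quantitative", "binary"),
                          n_cases = NA_integer_, n_controls = NA_integer_) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  if (trait_type == "binary" && !is.na(n_cases) && n_cases < 0)
    stop("n_cases must be >= 0")
  for (col in .SUMSTAT_COLS) {
    if (!col %in% names(records))
      records[[col]] <- if (col %in% c("variant_id", "chr", "ea", "oa"))
        NA_character_ else NA_real_
  }
  records <- records[.SUMSTAT_COLS]
  v <- .validate_records(records)
  structure(
    list(trait_id = trait_id, trait_type = trait_type,
         n_cases = n_cases, n_controls = n_controls, records = v$records),
    drop_log = v$dropped, class = "summary_stats")
}

# Enforce VariantAssociation invariants; returns kept records + drop counts.
.validate_records <- function(rec) {
  rec$variant_id <- as.character(rec$variant_id)
  rec$chr <- as.character(rec$chr)
  rec$ea <- toupper(as.character(rec$ea))
  rec$oa <- toupper(as.character(rec$oa))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    rec[[col]] <- as.numeric(rec[[col]])

  nuc <- c("A", "C", "G", "T")
  bad_allele <- !(rec$ea %in% nuc) | !(rec$oa %in% nuc) | rec$ea == rec$oa
  bad_se     <- is.na(rec$se) | rec$se <= 0
  bad_p      <- is.na(rec$pval) | rec$pval <= 0 | rec$pval > 1
  bad_beta   <- is.na(rec$beta) | !is.finite(rec$beta)
  bad_eaf    <- !is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1)
  bad_pos    <- !is.na(rec$pos) & rec$pos < 1
  bad_id     <- is.na(rec$variant_id) | rec$variant_id == ""
  bad <- bad_allele | bad_se | bad_p | bad_beta | bad_eaf | bad_pos | bad_id
  bad[is.na(bad)] <- TRUE
  kept <- .df_rows(rec, !bad)
  dup <- duplicated(kept$variant_id)
  dropped <- c(invalid_allele = sum(bad_allele, na.rm = TRUE),
               nonpositive_se = sum(bad_se, na.rm = TRUE),
               invalid_pvalue = sum(bad_p, na.rm = TRUE),
               invalid_beta   = sum(bad_beta, na.rm = TRUE),
               invalid_eaf    = sum(bad_eaf, na.rm = TRUE),
               invalid_pos    = sum(bad_pos, na.rm = TRUE),
               missing_id     = sum(bad_id, na.rm = TRUE),
               duplicate_id   = sum(dup))
  if (any(dup)) kept <- .df_rows(kept, !dup)
  list(records = kept, dropped = dropped)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s' (%s): %d variants\n",
              x$trait_id, x$trait_type, nrow(x$records)))
  if (x$trait_type == "binary" && !is.na(x$n_cases))
    cat(sprintf("  cases/controls: %s / %s\n", x$n_cases, x$n_controls))
  invisible(x)
}

#' Number of dropped records per validation reason
#' @param stats A `summary_stats` object.
#' @return Named integer vector of drop counts.
#' @export
drop_log <- function(stats) attr(stats, "drop_log")

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text table (tab- or comma-separated, inferred from the
#' file extension unless `sep` is given) into a validated [summary_stats()]
#' object. Mandatory columns — variant id, both alleles, beta, SE, p-value —
#' must be resolvable through `dialect`; chromosome, position, frequency and
#' sample size are optional. `"."` and empty fields are read as missing.
#'
#' @param path File path.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @param trait_id Trait identifier; defaults to the file name.
#' @param trait_type,n_cases,n_controls Trait metadata, see
#'   [summary_stats()].
#' @param sep Field separator; `NULL` infers `","` for `.csv`, tab
#'   otherwise.
#' @return A `summary_stats` object; invalid rows are dropped and counted in
#'   [drop_log()].
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_id = NULL,
                          trait_type = c("quantitative", "binary"),
                          n_cases = NA_integer_, n_controls = NA_integer_,
                          sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          na.strings = c("NA", ".", ""),
                          check.names = FALSE, comment.char = "")
  if (nrow(df) == 0L) stop("empty input: no data rows in ", path)
  mandatory <- c("variant_id", "ea", "oa", "beta", "se", "pval")
  for (field in names(sumstats_dialect())) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(df)) {
      if (field %in% mandatory)
        stop(sprintf("mandatory column '%s' (field %s) not found in %s",
                     col %||% field, field, path))
      df[[field]] <- NA
    } else if (col != field) {
      df[[field]] <- df[[col]]
    }
  }
  if (is.null(trait_id)) trait_id <- sub("\\.[^.]*$", "", basename(path))
  summary_stats(trait_id, df[.SUMSTAT_COLS], trait_type = trait_type,
                n_cases = n_cases, n_controls = n_controls)
}

#' Write a summary-statistics table as canonical TSV
#'
#' Fixed column order (`variant_id chr pos ea oa eaf beta se pval n`), UTF-8,
#' `"."` for missing values, numerics to 10 significant digits. Reading the
#' file back with [read_sumstats()] reproduces every record.
#'
#' @param stats A `summary_stats` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  rec <- stats$records
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- sprintf("%.10g", x)
    } else {
      out <- as.character(x)
    }
    out[is.na(x)] <- "."
    out
  }
  out <- vapply(rec, fmt, character(nrow(rec) %||% 0L))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(.SUMSTAT_COLS, collapse = "\t"), con)
  if (nrow(rec) > 0L)
    writeLines(apply(matrix(out, nrow = nrow(rec)), 1L, paste,
                     collapse = "\t"), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gene annotations for cis-window definition
#'
#' Accepts a 4-column table `gene, chr, start, end` (TSV, 1-based inclusive
#' coordinates) or a BED file (`chr, start, end, gene`, 0-based half-open,
#' converted to 1-based inclusive on read). Rows with `start > end` are
#' rejected with a warning.
#'
#' @param path File path.
#' @param format `"tsv"` or `"bed"`.
#' @return Data frame with columns `gene_id`, `chr`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_annotations <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            col.names = c("chr", "start", "end", "gene_id"),
                            colClasses = c("character", "numeric", "numeric",
                                           "character"))
    df$start <- df$start + 1  # 0-based half-open -> 1-based inclusive
    df <- df[c("gene_id", "chr", "start", "end")]
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character",
                                           "numeric", "numeric"))
    names(df) <- c("gene_id", "chr", "start", "end")
  }
  bad <- df$start > df$end
  if (any(bad)) {
    warning(sum(bad), " gene annotation row(s) with start > end rejected")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write gene annotations as 4-column TSV
#'
#' Inverse of [read_gene_annotations()] (TSV form, 1-based inclusive).
#'
#' @param genes Data frame with `gene_id`, `chr`, `start`, `end`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_annotations <- function(genes, path) {
  utils::write.table(
    data.frame(gene = genes$gene_id, chr = genes$chr,
               start = sprintf("%.10g", genes$start),
               end = sprintf("%.10g", genes$end)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
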