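# Internal fast data-frame helpers: data.frame() and [.data.frame carry
# substantial interpreter overhead that dominates screening-scale loops;
# these build/subset plain data frames without checks (inputs are
# internally generated and already consistent).

.df <- function(...) {
  l <- list(...)
  n <- if (length(l)) length(l[[1L]]) else 0L
  structure(l, class = "data.frame", row.names = .set_row_names(n))
}

.df_rows <- function(df, keep) {
  structure(lapply(df, `[`, keep), class = "data.frame",
            row.names = .set_row_names(if (is.logical(keep)) sum(keep)
                                       else length(keep)))
}
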