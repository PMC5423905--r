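# internal helpers

# stop with a consistent error class so callers can test on it
ss_abort <- function(msg, class = "splicescape_error") {
  rlang::abort(msg, class = class)
}

assert_cols <- function(x, cols, what = deparse(substitute(x))) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) {
    ss_abort(sprintf("%s is missing required column(s): %s",
                     what, paste(miss, collapse = ", ")))
  }
  invisible(x)
}

# collapse/expand comma-separated id sets (kept as plain strings so event
# tables serialize to TSV without list-columns)
collapse_ids <- function(x) paste(sort(unique(x)), collapse = ",")

split_ids <- function(x) {
  if (length(x) == 1) return(strsplit(x, ",", fixed = TRUE)[[1]])
  strsplit(x, ",", fixed = TRUE)
}

interval_key <- function(start, end) sprintf("%d-%d", start, end)

# half-open interval overlap
overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
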