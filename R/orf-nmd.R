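#' Find an open reading frame from the canonical start
#'
#' If `canonical_start` is supplied and an ATG sits at that transcript
#' offset, translation starts there (the isoform "shares the canonical
#' start"); otherwise the longest ATG-initiated ORF is taken, ties broken
#' to the 5'-most start. The CDS runs to the first in-frame stop codon
#' (inclusive) or, with no stop, to the last complete codon.
#'
#' @param seq Spliced transcript sequence over A/C/G/T/N.
#' @param canonical_start Optional 0-based transcript offset of the
#'   annotated canonical start codon.
#' @return A one-row tibble: `cds_start`, `cds_end` (0-based half-open
#'   transcript coordinates; `NA` when non-coding), `has_stop`,
#'   `shares_canonical_start`, `noncoding`.
#' @export
find_orf <- function(seq, canonical_start = NULL) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) ss_abort("sequence must be over A/C/G/T/N")
  n <- nchar(seq)
  orf_from <- function(s0) {  # 0-based start at an ATG
    stops <- c("TAA", "TAG", "TGA")
    i <- s0 + 3L
    while (i + 3L <= n) {
      if (substr(seq, i + 1L, i + 3L) %in% stops) {
        return(list(end = i + 3L, has_stop = TRUE))
      }
      i <- i + 3L
    }
    list(end = s0 + 3L * ((n - s0) %/% 3L), has_stop = FALSE)
  }
  noncoding_call <- tibble(cds_start = NA_integer_, cds_end = NA_integer_,
                           has_stop = FALSE, shares_canonical_start = FALSE,
                           noncoding = TRUE)
  if (!is.null(canonical_start) && !is.na(canonical_start) &&
      canonical_start + 3L <= n &&
      substr(seq, canonical_start + 1L, canonical_start + 3L) == "ATG") {
    o <- orf_from(as.integer(canonical_start))
    return(tibble(cds_start = as.integer(canonical_start),
                  cds_end = as.integer(o$end), has_stop = o$has_stop,
                  shares_canonical_start = TRUE, noncoding = FALSE))
  }
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (starts[1] == -1) return(noncoding_call)
  best <- NULL
  for (s in as.integer(starts) - 1L) {
    o <- orf_from(s)
    if (is.null(best) || (o$end - s) > (best$end - best$s)) {
      best <- list(s = s, end = o$end, has_stop = o$has_stop)
    }
  }
  tibble(cds_start = best$s, cds_end = as.integer(best$end),
         has_stop = best$has_stop, shares_canonical_start = FALSE,
         noncoding = FALSE)
}

#' Call a transcript as a nonsense-mediated-decay candidate
#'
#' Implements the 50-nt rule: an isoform is an NMD candidate when its ORF
#' shares the canonical start, terminates at a stop codon, and that stop
#' lies more than 50 nt (strictly) upstream of the last exon-exon junction
#' in transcript coordinates. Single-exon transcripts are never candidates.
#'
#' @param exons_t Exon tibble for one transcript.
#' @param orf One-row tibble from [find_orf()].
#' @return Logical.
#' @export
classify_nmd <- function(exons_t, orf) {
  exons_t <- validate_exons(exons_t)
  if (nrow(exons_t) < 2) return(FALSE)
  if (orf$noncoding || !orf$shares_canonical_start || !orf$has_stop) return(FALSE)
  lens <- exons_t$end - exons_t$start
  if (exons_t$strand[1] == "-") lens <- rev(lens)
  last_junction <- sum(lens) - lens[length(lens)]
  (last_junction - orf$cds_end) > 50
}

#' Map a transcript-coordinate CDS to genomic intervals
#'
#' @param exons_t Exon tibble for one transcript.
#' @param cds_start,cds_end 0-based half-open transcript coordinates.
#' @return A tibble of genomic intervals (`chrom`, `start`, `end`).
#' @export
cds_genomic <- function(exons_t, cds_start, cds_end) {
  exons_t <- validate_exons(exons_t)
  lens <- exons_t$end - exons_t$start
  if (exons_t$strand[1] == "-") {
    ex <- exons_t[rev(seq_len(nrow(exons_t))), ]
  } else {
    ex <- exons_t
  }
  lens <- ex$end - ex$start
  offs <- cumsum(c(0L, lens))[seq_len(nrow(ex))]
  out <- list()
  for (i in seq_len(nrow(ex))) {
    lo <- max(cds_start, offs[i]); hi <- min(cds_end, offs[i] + lens[i])
    if (lo >= hi) next
    if (ex$strand[1] == "+") {
      gs <- ex$start[i] + (lo - offs[i]); ge <- ex$start[i] + (hi - offs[i])
    } else {
      ge <- ex$end[i] - (lo - offs[i]); gs <- ex$end[i] - (hi - offs[i])
    }
    out[[length(out) + 1]] <- tibble(chrom = ex$chrom[i], start = gs, end = ge)
  }
  bind_rows(out) %>% arrange(.data$start)
}

#' Localize events to coding or untranslated regions
#'
#' An event overlapping the canonical CDS genomic span (minimum to maximum
#' CDS coordinate) is `CDS`; events strictly outside the span are `UTR5` or
#' `UTR3` by transcription-order position; genes without a CDS give
#' `noncoding`.
#'
#' @param events Event tibble from [detect_events()].
#' @param cds_intervals Tibble of canonical CDS genomic intervals with
#'   columns `gene_id`, `start`, `end` (may have zero rows for a gene).
#' @return `events` with a `region` column.
#' @export
localize_event <- function(events, cds_intervals) {
  assert_cols(cds_intervals, c("gene_id", "start", "end"))
  span <- if (nrow(cds_intervals) == 0) {
    tibble(gene_id = character(), cds_lo = integer(), cds_hi = integer())
  } else {
    cds_intervals %>%
      group_by(.data$gene_id) %>%
      summarise(cds_lo = min(.data$start), cds_hi = max(.data$end),
                .groups = "drop")
  }
  events %>%
    left_join(span, by = "gene_id") %>%
    mutate(region = dplyr::case_when(
      is.na(.data$cds_lo) ~ "noncoding",
      overlaps(.data$affected_start, .data$affected_end,
               .data$cds_lo, .data$cds_hi) ~ "CDS",
      .data$affected_end <= .data$cds_lo & .data$strand == "+" ~ "UTR5",
      .data$affected_end <= .data$cds_lo & .data$strand == "-" ~ "UTR3",
      .data$affected_start >= .data$cds_hi & .data$strand == "+" ~ "UTR3",
      TRUE ~ "UTR5"
    )) %>%
    select(-"cds_lo", -"cds_hi")
}

#' Frame preservation of events
#'
#' An event preserves reading frame when the affected length (retained
#' intron, skipped exon, or distance between competing splice sites) is a
#' multiple of 3. Undefined (`NA`) for `AltTE`.
#'
#' @param events Event tibble.
#' @return `events` with a logical `frame_preserving` column.
#' @export
frame_preserving <- function(events) {
  events %>%
    mutate(frame_preserving = if_else(
      .data$event_type == "AltTE", NA,
      (.data$affected_end - .data$affected_start) %% 3L == 0L))
}
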