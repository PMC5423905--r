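#' Build splice anchor sequence tags (SASTs) for events
#'
#' For each event, extracts up to `max_anchor` nucleotides of genomic
#' sequence on each side of the event's defining junction span (the first
#' flanking junction's start to the last flanking junction's end),
#' truncated at the gene boundaries to avoid intergenic homology. Anchors
#' from `-` strand genes are reverse-complemented so both anchors read in
#' transcription orientation; the "upstream" anchor is 5' of the event in
#' transcription order.
#'
#' @param events Event tibble (needs `event_id`, `gene_id`, `chrom`,
#'   `strand`, `event_type`, `junctions`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param gene_bounds Tibble from [gene_loci()] (uses `gene_id`, `start`,
#'   `end`).
#' @param max_anchor Maximum anchor length in nt (default 300).
#' @return Tibble: `event_id`, `gene_id`, `event_type`, `upstream`,
#'   `downstream` (anchor sequences). Errors if an anchor would be empty.
#' @export
make_sast <- function(events, genome, gene_bounds, max_anchor = 300) {
  assert_cols(events, c("event_id", "gene_id", "chrom", "strand",
                        "event_type", "junctions"))
  gb <- setNames(split(gene_bounds, seq_len(nrow(gene_bounds))),
                 gene_bounds$gene_id)
  chrom_cache <- vapply(unique(events$chrom), function(ch) {
    if (!ch %in% names(genome)) ss_abort(sprintf("chrom %s not in genome", ch))
    as.character(genome[[ch]])
  }, character(1))
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    g <- gb[[e$gene_id]]
    if (is.null(g)) ss_abort(sprintf("gene %s not in gene_bounds", e$gene_id))
    jj <- do.call(rbind, lapply(strsplit(e$junctions, ";")[[1]], function(k) {
      as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
    }))
    j_lo <- min(jj[, 1]); j_hi <- max(jj[, 2])
    left_s <- max(g$start, j_lo - max_anchor)
    right_e <- min(g$end, j_hi + max_anchor)
    if (left_s >= j_lo || j_hi >= right_e) {
      ss_abort(sprintf("event %s: empty anchor at gene boundary", e$event_id))
    }
    chrom_seq <- chrom_cache[[e$chrom]]
    left <- substring(chrom_seq, left_s + 1L, j_lo)
    right <- substring(chrom_seq, j_hi + 1L, right_e)
    if (e$strand == "-") {
      rc <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
      tibble(event_id = e$event_id, gene_id = e$gene_id,
             event_type = e$event_type,
             upstream = rc(right), downstream = rc(left))
    } else {
      tibble(event_id = e$event_id, gene_id = e$gene_id,
             event_type = e$event_type, upstream = left, downstream = right)
    }
  })
  bind_rows(rows)
}

.align_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.align_cache$BLOSUM62)) {
    utils::data("BLOSUM62", package = "Biostrings", envir = .align_cache)
  }
  .align_cache$BLOSUM62
}

six_frame_translate <- function(seq) {
  d <- Biostrings::DNAString(seq)
  # the fuzzy-codon path rebuilds a genetic-code table per call; only pay
  # for it when ambiguity codes are actually present
  fuzzy <- grepl("[^ACGT]", seq)
  out <- character(0)
  for (strand in 1:2) {
    dd <- if (strand == 1) d else Biostrings::reverseComplement(d)
    for (f in 1:3) {
      len <- length(dd) - f + 1L
      len <- len - len %% 3L
      if (len >= 3) {
        codons <- Biostrings::subseq(dd, f, f + len - 1L)
        aa <- if (fuzzy) {
          suppressWarnings(Biostrings::translate(codons,
                                                 if.fuzzy.codon = "solve"))
        } else {
          Biostrings::translate(codons)
        }
        out <- c(out, as.character(aa))
      }
    }
  }
  Biostrings::AAStringSet(out)
}

#' Translated local alignment of two anchors
#'
#' All 6x6 frame pairs of both nucleotide sequences are translated and
#' aligned with Smith-Waterman local alignment (BLOSUM62, gap open 11,
#' extend 1); the best-scoring frame pair is reported. The E-value uses
#' Karlin-Altschul statistics `E = K m n exp(-lambda S)` with gapped
#' BLOSUM62 constants `lambda = 0.267`, `K = 0.041` and the nucleotide
#' search space `m * n`.
#'
#' @param a,b Nucleotide anchor sequences (>= 3 nt).
#' @param lambda,K Karlin-Altschul constants.
#' @param early_exit_evalue Optional: stop scanning frame pairs as soon as
#'   one reaches this E-value; the reported best is then the best seen so
#'   far. Used by the triplet classifier, where only threshold crossing
#'   matters.
#' @return One-row tibble: `score`, `evalue`, `aligned_nt_a`,
#'   `aligned_nt_b` (3x the aligned amino-acid spans).
#' @export
translated_align <- function(a, b, lambda = 0.267, K = 0.041,
                             early_exit_evalue = NULL) {
  if (nchar(a) < 3 || nchar(b) < 3) ss_abort("anchors must be >= 3 nt")
  fa <- six_frame_translate(a)
  fb <- six_frame_translate(b)
  stop_score <- if (is.null(early_exit_evalue)) Inf else {
    (log(K * nchar(a) * nchar(b)) - log(early_exit_evalue)) / lambda
  }
  best <- list(score = -Inf, i = 1L, j = 1L)
  for (j in seq_along(fb)) {
    sc <- Biostrings::pairwiseAlignment(
      fa, fb[[j]], type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    if (max(sc) > best$score) {
      best <- list(score = max(sc), i = which.max(sc), j = j)
    }
    if (best$score >= stop_score) break
  }
  al <- Biostrings::pairwiseAlignment(
    fa[[best$i]], fb[[best$j]], type = "local",
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
  pat <- Biostrings::pattern(al)
  sub <- Biostrings::subject(al)
  tibble(
    score = Biostrings::score(al),
    evalue = K * nchar(a) * nchar(b) * exp(-lambda * Biostrings::score(al)),
    aligned_nt_a = 3L * (Biostrings::end(pat) - Biostrings::start(pat) + 1L),
    aligned_nt_b = 3L * (Biostrings::end(sub) - Biostrings::start(sub) + 1L))
}

# best pairwise SAST match between two members' same-type events:
# aligns upstream-vs-upstream and downstream-vs-downstream anchors and
# keeps the smallest E over event pairs and sides
best_member_match <- function(sast_x, sast_y, e_max, e_max_short, short_len) {
  best <- NULL
  for (i in seq_len(nrow(sast_x))) for (j in seq_len(nrow(sast_y))) {
    for (side in c("upstream", "downstream")) {
      a <- sast_x[[side]][i]; b <- sast_y[[side]][j]
      thr <- if (nchar(a) < short_len && nchar(b) < short_len) {
        e_max_short
      } else {
        e_max
      }
      al <- translated_align(a, b, early_exit_evalue = thr)
      al$matched <- al$evalue <= thr
      al$event_x <- sast_x$event_id[i]; al$event_y <- sast_y$event_id[j]
      if (al$matched) return(al)
      if (is.null(best) || al$evalue < best$evalue) best <- al
    }
  }
  best
}

#' Classify conserved splicing events within ortholog triplets
#'
#' For each triplet (maize subgenome1 homeolog, subgenome2 homeolog,
#' sorghum ortholog) and each event type present, SAST anchors of
#' same-type events are aligned pairwise between members
#' ([translated_align()]). A pair matches when the best E-value is at most
#' `e_max` (relaxed to `e_max_short` when both anchors are shorter than
#' `short_len` nt). Calls whose aligned span is below `min_aligned` nt in
#' at least two members are discarded. Categories:
#'
#' 1. conserved in subgenome1, subgenome2 and sorghum (both maize-sorghum
#'    pairs match);
#' 2. conserved between subgenome1 and sorghum, absent from subgenome2;
#' 3. conserved between subgenome2 and sorghum, absent from subgenome1;
#' 4. conserved between the maize homeologs, absent from sorghum.
#'
#' @param triplets Tibble: `triplet_id`, `maize1_gene`, `maize2_gene`,
#'   `sorghum_gene`.
#' @param sasts SAST tibble from [make_sast()] with an extra `genome`
#'   column in `maize1`/`maize2`/`sorghum`.
#' @param e_max E-value threshold (default 1e-5).
#' @param e_max_short Relaxed threshold for short anchors (default 1e-2).
#' @param short_len Anchor length (nt) below which the relaxed threshold
#'   applies (default 100).
#' @param min_aligned Minimum aligned span in nt (default 30).
#' @return Tibble of conservation calls: `triplet_id`, `event_type`,
#'   `category`, match flags and E-values per pair, `n_member_events`,
#'   `genes`.
#' @export
classify_triplet_events <- function(triplets, sasts, e_max = 1e-5,
                                    e_max_short = 1e-2, short_len = 100,
                                    min_aligned = 30) {
  assert_cols(triplets, c("triplet_id", "maize1_gene", "maize2_gene",
                          "sorghum_gene"))
  assert_cols(sasts, c("event_id", "gene_id", "event_type", "genome",
                       "upstream", "downstream"))
  out <- list()
  for (t in seq_len(nrow(triplets))) {
    tr <- triplets[t, ]
    member <- list(
      maize1 = sasts %>% filter(.data$genome == "maize1",
                                .data$gene_id == tr$maize1_gene),
      maize2 = sasts %>% filter(.data$genome == "maize2",
                                .data$gene_id == tr$maize2_gene),
      sorghum = sasts %>% filter(.data$genome == "sorghum",
                                 .data$gene_id == tr$sorghum_gene))
    types <- unique(unlist(lapply(member, function(m) m$event_type)))
    for (ty in types) {
      mt <- lapply(member, function(m) m[m$event_type == ty, , drop = FALSE])
      has <- vapply(mt, nrow, 0L) > 0
      pair <- function(x, y) {
        if (!has[[x]] || !has[[y]]) return(NULL)
        best_member_match(mt[[x]], mt[[y]], e_max, e_max_short, short_len)
      }
      m1s <- pair("maize1", "sorghum")
      m2s <- pair("maize2", "sorghum")
      m12 <- pair("maize1", "maize2")
      ok <- function(m) !is.null(m) && m$matched
      category <- if (ok(m1s) && ok(m2s)) 1L
        else if (ok(m1s) && !has[["maize2"]]) 2L
        else if (ok(m2s) && !has[["maize1"]]) 3L
        else if (ok(m12) && !has[["sorghum"]]) 4L
        else NA_integer_
      if (is.na(category)) next
      # aligned-length rule: the aligned span must reach min_aligned nt in
      # at least two of the members supporting the call
      spans <- c(
        maize1 = max(0, m1s$aligned_nt_a %||% 0, m12$aligned_nt_a %||% 0),
        maize2 = max(0, m2s$aligned_nt_a %||% 0, m12$aligned_nt_b %||% 0),
        sorghum = max(0, m1s$aligned_nt_b %||% 0, m2s$aligned_nt_b %||% 0))
      spans <- spans[has[names(spans)]]
      if (sum(spans < min_aligned) >= 2) next
      members_in <- switch(category,
        c("maize1", "maize2", "sorghum"),
        c("maize1", "sorghum"),
        c("maize2", "sorghum"),
        c("maize1", "maize2"))
      genes <- c(maize1 = tr$maize1_gene, maize2 = tr$maize2_gene,
                 sorghum = tr$sorghum_gene)[members_in]
      out[[length(out) + 1]] <- tibble(
        triplet_id = tr$triplet_id, event_type = ty, category = category,
        e_m1_s = m1s$evalue %||% NA_real_,
        e_m2_s = m2s$evalue %||% NA_real_,
        e_m1_m2 = m12$evalue %||% NA_real_,
        n_member_events = sum(vapply(mt[members_in], nrow, 0L)),
        genes = paste(genes, collapse = ","))
    }
  }
  if (length(out) == 0) {
    return(tibble(triplet_id = character(), event_type = character(),
                  category = integer(), e_m1_s = double(), e_m2_s = double(),
                  e_m1_m2 = double(), n_member_events = integer(),
                  genes = character()))
  }
  bind_rows(out)
}

#' Summarise conservation calls per category and event type
#'
#' Each call corresponds to one cluster of matched SASTs within a triplet
#' and event type; the summary counts clusters, member events, and
#' distinct contributing genes, mirroring the standard
#' clusters/events/genes conservation table.
#'
#' @param calls Tibble from [classify_triplet_events()].
#' @return Tibble: `event_type`, `category`, `clusters`, `events`,
#'   `genes`.
#' @export
summarize_conservation <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(event_type = character(), category = integer(),
                  clusters = integer(), events = integer(), genes = integer()))
  }
  calls %>%
    group_by(.data$event_type, .data$category) %>%
    summarise(clusters = n(),
              events = sum(.data$n_member_events),
              genes = n_distinct(unlist(split_ids(.data$genes))),
              .groups = "drop") %>%
    arrange(.data$event_type, .data$category)
}
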