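#' Classify alternative-splicing events between two isoforms
#'
#' Compares two transcript models of the same gene and emits every
#' structural difference matching one of the five classical event types:
#'
#' * `IntronR` — an intron of one isoform is fully contained inside an exon
#'   of the other (the retained intron is the affected interval);
#' * `ExonS` — an internal exon of one isoform is absent from the other
#'   while both share the bounding donor and acceptor;
#' * `AltA` — two introns share their donor but differ at the acceptor;
#' * `AltD` — two introns share their acceptor but differ at the donor;
#'   for both, the segment between the competing sites must be exonic in
#'   the shorter-intron isoform (otherwise a skipped exon would also score
#'   as AltA + AltD through its shared flanking boundaries);
#' * `AltTE` — the terminal junctions at one transcript end differ and at
#'   least one isoform's terminal exon has no exonic overlap with the other
#'   isoform (the more distal qualifying terminal exon is the affected
#'   interval).
#'
#' Across all types, the "on" isoform set contains the affected interval as
#' exonic sequence (the intron-retaining isoform for `IntronR`, the
#' exon-including isoform for `ExonS`); "off" isoforms splice it out.
#' Differences matching none of the five definitions are ignored.
#'
#' @param exons_a,exons_b Exon tibbles for one transcript each; same gene,
#'   chromosome and strand.
#' @return A tibble of events with columns `gene_id`, `chrom`, `strand`,
#'   `event_type`, `affected_start`, `affected_end`, `junctions`
#'   (semicolon-separated `start-end` intron keys), `on_isoforms`,
#'   `off_isoforms` (comma-separated transcript ids).
#' @export
classify_pair <- function(exons_a, exons_b) {
  a <- as_chain(exons_a)
  b <- as_chain(exons_b)
  if (a$chrom != b$chrom || a$strand != b$strand) {
    ss_abort("isoforms must share chromosome and strand")
  }
  rows <- classify_chain_pair(a, b)
  if (length(rows) == 0) return(empty_events())
  ev <- bind_rows(rows)
  ev <- ev[!duplicated(ev[, c("event_type", "affected_start",
                              "affected_end", "junctions")]), ]
  tibble(gene_id = a$gene_id, chrom = a$chrom, strand = a$strand, ev)
}

# light-weight internal transcript representation: ordered exon vectors
as_chain <- function(ex, validated = FALSE) {
  if (!validated) {
    assert_cols(ex, c("transcript_id", "gene_id", "chrom", "start", "end",
                      "strand"), "exon table")
    if (length(unique(ex$transcript_id)) != 1) {
      ss_abort("expected exactly one transcript per table")
    }
    if (length(unique(ex$chrom)) != 1 || length(unique(ex$strand)) != 1) {
      ss_abort("invalid transcript model: mixed chrom/strand")
    }
  }
  o <- order(ex$start)
  s <- as.integer(ex$start[o]); e <- as.integer(ex$end[o])
  if (!validated) {
    if (any(s < 0) || any(e <= s)) ss_abort("invalid exon interval")
    if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
      ss_abort("overlapping exons within one transcript")
    }
  }
  list(tid = ex$transcript_id[1], gene_id = ex$gene_id[1],
       chrom = ex$chrom[1], strand = ex$strand[1], s = s, e = e,
       is = if (length(s) > 1) e[-length(e)] else integer(0),
       ie = if (length(s) > 1) s[-1] else integer(0))
}

empty_events <- function(...) {
  tibble(gene_id = character(), chrom = character(), strand = character(),
         event_type = character(), affected_start = integer(),
         affected_end = integer(), junctions = character(),
         on_isoforms = character(), off_isoforms = character())
}

event_row <- function(type, as, ae, jx, on, off) {
  data.frame(event_type = type, affected_start = as, affected_end = ae,
             junctions = jx, on_isoforms = on, off_isoforms = off,
             stringsAsFactors = FALSE)
}

classify_chain_pair <- function(a, b) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  strand <- a$strand

  # intron retention: intron of x inside an exon of y (on = y)
  for (xy in list(list(a, b), list(b, a))) {
    x <- xy[[1]]; y <- xy[[2]]
    for (i in seq_along(x$is)) {
      if (any(y$s <= x$is[i] & x$ie[i] <= y$e)) {
        add(event_row("IntronR", x$is[i], x$ie[i],
                      interval_key(x$is[i], x$ie[i]), y$tid, x$tid))
      }
    }
  }

  # exon skipping: internal exon of x absent from y, shared bounding sites
  for (xy in list(list(a, b), list(b, a))) {
    x <- xy[[1]]; y <- xy[[2]]
    n <- length(x$s)
    if (n < 3 || length(y$is) == 0) next
    for (k in 2:(n - 1)) {
      spanned <- any(y$is == x$e[k - 1] & y$ie == x$s[k + 1])
      absent <- !any(x$s[k] < y$e & y$s < x$e[k])
      if (spanned && absent) {
        add(event_row("ExonS", x$s[k], x$e[k],
                      paste(interval_key(x$e[k - 1], x$s[k]),
                            interval_key(x$e[k], x$s[k + 1]), sep = ";"),
                      x$tid, y$tid))
      }
    }
  }

  # competing donors/acceptors: intron pairs sharing exactly one boundary;
  # the inter-site segment must be exonic in the shorter-intron isoform
  for (i in seq_along(a$is)) for (j in seq_along(b$is)) {
    ss <- a$is[i] == b$is[j]
    se <- a$ie[i] == b$ie[j]
    if (ss == se) next
    if (ss) {
      type <- if (strand == "+") "AltA" else "AltD"
      lo <- min(a$ie[i], b$ie[j]); hi <- max(a$ie[i], b$ie[j])
      shorter <- if (a$ie[i] < b$ie[j]) a else b
      longer <- if (a$ie[i] < b$ie[j]) b else a
    } else {
      type <- if (strand == "+") "AltD" else "AltA"
      lo <- min(a$is[i], b$is[j]); hi <- max(a$is[i], b$is[j])
      shorter <- if (a$is[i] > b$is[j]) a else b
      longer <- if (a$is[i] > b$is[j]) b else a
    }
    if (!any(shorter$s <= lo & hi <= shorter$e)) next
    add(event_row(type, lo, hi,
                  paste(sort(c(interval_key(a$is[i], a$ie[i]),
                               interval_key(b$is[j], b$ie[j]))),
                        collapse = ";"),
                  shorter$tid, longer$tid))
  }

  # alternate terminal exons; both isoforms need a terminal junction
  if (length(a$is) > 0 && length(b$is) > 0) {
    na <- length(a$s); nb <- length(b$s)
    for (side in c("5p", "3p")) {
      genomic_first <- (side == "5p") == (strand == "+")
      ia <- if (genomic_first) 1L else length(a$is)
      ib <- if (genomic_first) 1L else length(b$is)
      if (a$is[ia] == b$is[ib] && a$ie[ia] == b$ie[ib]) next
      ta_i <- if (genomic_first) 1L else na
      tb_i <- if (genomic_first) 1L else nb
      a_free <- !any(a$s[ta_i] < b$e & b$s < a$e[ta_i])
      b_free <- !any(b$s[tb_i] < a$e & a$s < b$e[tb_i])
      if (!a_free && !b_free) next
      cs <- c(if (a_free) a$s[ta_i], if (b_free) b$s[tb_i])
      ce <- c(if (a_free) a$e[ta_i], if (b_free) b$e[tb_i])
      owner <- c(if (a_free) a$tid, if (b_free) b$tid)
      pick <- if (genomic_first) which.min(cs) else which.max(ce)
      other <- if (owner[pick] == a$tid) b$tid else a$tid
      add(event_row("AltTE", cs[pick], ce[pick],
                    paste(sort(c(interval_key(a$is[ia], a$ie[ia]),
                                 interval_key(b$is[ib], b$ie[ib]))),
                          collapse = ";"),
                    owner[pick], other))
    }
  }
  rows
}

#' Detect alternative-splicing events across all isoforms of each gene
#'
#' Runs the pairwise classifier over every transcript pair within each
#' gene and deduplicates events by (type, affected interval, junction
#' key). The on/off isoform sets accumulate every supporting isoform, so
#' downstream ratio quantification can sum expression over all "on" and
#' all "off" isoforms of a shared event.
#'
#' @param exons Exon tibble covering one or more genes.
#' @return A tibble of deduplicated events with an `event_id` column
#'   (`<gene_id>.e<k>`). Genes with a single transcript contribute no rows.
#' @export
detect_events <- function(exons) {
  exons <- validate_exons(exons)
  out <- list()
  for (gx in split(exons, exons$gene_id)) {
    ge <- detect_events_one_gene(gx)
    if (!is.null(ge)) out[[length(out) + 1L]] <- ge
  }
  if (length(out) == 0) {
    return(bind_cols(tibble(event_id = character()), empty_events()))
  }
  ev <- bind_rows(out)
  ev %>%
    group_by(.data$gene_id) %>%
    mutate(event_id = sprintf("%s.e%d", .data$gene_id, row_number())) %>%
    ungroup() %>%
    select("event_id", dplyr::everything())
}

detect_events_one_gene <- function(gx) {
  chains <- lapply(split(gx, gx$transcript_id), as_chain, validated = TRUE)
  if (length(chains) < 2) return(NULL)
  rows <- list()
  for (i in seq_len(length(chains) - 1)) {
    for (j in (i + 1):length(chains)) {
      pr <- classify_chain_pair(chains[[i]], chains[[j]])
      if (length(pr) > 0) rows <- c(rows, pr)
    }
  }
  if (length(rows) == 0) return(NULL)
  ev <- bind_rows(rows)
  key <- paste(ev$event_type, ev$affected_start, ev$affected_end,
               ev$junctions, sep = "\r")
  merged <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    r <- ev[idx[1], ]
    r$on_isoforms <- collapse_ids(ev$on_isoforms[idx])
    r$off_isoforms <- collapse_ids(ev$off_isoforms[idx])
    r
  })
  ev <- bind_rows(merged)
  ev <- ev[order(ev$affected_start, ev$event_type, ev$junctions), ]
  tibble(gene_id = gx$gene_id[1], chrom = gx$chrom[1],
         strand = gx$strand[1], ev)
}

#' Export events as TSV
#'
#' @param events Event tibble from [detect_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
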