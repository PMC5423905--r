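#' Validate a table of transcript exons
#'
#' Exon tables are the package's core representation of transcript models:
#' one row per exon with columns `transcript_id`, `gene_id`, `chrom`,
#' `start`, `end`, `strand`. Coordinates are 0-based, half-open throughout
#' the package; on-disk GTF (1-based, inclusive) is converted at the I/O
#' boundary.
#'
#' @param exons A data frame of exons.
#' @return The exon table as a tibble, sorted by transcript and start.
#'   Errors if any exon is empty or negative, if a transcript spans several
#'   chromosomes or strands, or if exons of one transcript overlap.
#' @export
validate_exons <- function(exons) {
  assert_cols(exons, c("transcript_id", "gene_id", "chrom", "start", "end",
                       "strand"), "exon table")
  exons <- as_tibble(exons) %>% arrange(.data$transcript_id, .data$start)
  if (any(exons$start < 0) || any(exons$end <= exons$start)) {
    ss_abort("invalid exon interval: require 0 <= start < end")
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    ss_abort("exon strand must be '+' or '-'")
  }
  bad <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      n_chrom = n_distinct(.data$chrom),
      n_strand = n_distinct(.data$strand),
      overlap = any(.data$start < lag(.data$end, default = -1L)),
      .groups = "drop"
    ) %>%
    filter(.data$n_chrom > 1 | .data$n_strand > 1 | .data$overlap)
  if (nrow(bad) > 0) {
    ss_abort(sprintf(
      "invalid transcript model(s): %s (mixed chrom/strand or overlapping exons)",
      paste(bad$transcript_id, collapse = ", ")))
  }
  exons
}

#' Read transcript models from a GTF file
#'
#' Reads exon features, converts 1-based inclusive GTF coordinates to the
#' package's 0-based half-open convention, and validates the resulting
#' transcript models.
#'
#' @param path Path to a GTF file with exon features carrying `gene_id` and
#'   `transcript_id` attributes.
#' @return A tibble of exons (see [validate_exons()]).
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    ss_abort(sprintf("malformed GTF line %d in %s",
                     which(body)[which(nfield < 9)[1]], path))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) ss_abort(sprintf("no exon features in %s", path))
  tibble(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) %>% validate_exons()
}

#' Write transcript models to a GTF file
#'
#' @param exons Exon tibble (0-based half-open); written as 1-based
#'   inclusive GTF exon features.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  exons <- validate_exons(exons)
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = exons$strand,
    type = "exon",
    gene_id = exons$gene_id,
    transcript_id = exons$transcript_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Summarise gene loci and their canonical transcripts
#'
#' The canonical transcript of a gene is the one with the longest spliced
#' (summed exonic) length; ties break to the lexicographically smallest
#' transcript id.
#'
#' @param exons Exon tibble.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (gene span), `n_transcripts`, `canonical_id`.
#' @export
gene_loci <- function(exons) {
  exons <- validate_exons(exons)
  lens <- exons %>%
    group_by(.data$gene_id, .data$transcript_id) %>%
    summarise(len = sum(.data$end - .data$start), .groups = "drop") %>%
    arrange(.data$gene_id, dplyr::desc(.data$len), .data$transcript_id)
  canon <- lens %>%
    group_by(.data$gene_id) %>%
    summarise(canonical_id = first(.data$transcript_id),
              n_transcripts = n(), .groups = "drop")
  span <- exons %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  left_join(span, canon, by = "gene_id")
}

#' Enumerate splice junctions (introns) of transcript models
#'
#' One junction per inter-exon gap, in transcription order. The donor is the
#' first intron base in transcription order (`intron_start` on `+`,
#' `intron_end - 1` on `-`); the acceptor is the last.
#'
#' @param exons Exon tibble (one or many transcripts).
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `intron_start`, `intron_end`, `donor_pos`, `acceptor_pos`,
#'   ordered by transcript and transcription order. Single-exon transcripts
#'   contribute no rows.
#' @export
introns_of <- function(exons) {
  exons <- validate_exons(exons)
  j <- exons %>%
    group_by(.data$transcript_id) %>%
    mutate(next_start = lead(.data$start)) %>%
    filter(!is.na(.data$next_start)) %>%
    ungroup() %>%
    transmute_introns()
  ord <- ifelse(j$strand == "+", j$intron_start, -j$intron_start)
  j %>% mutate(.ord = ord) %>%
    arrange(.data$transcript_id, .data$.ord) %>%
    select(-".ord")
}

transmute_introns <- function(x) {
  tibble(
    transcript_id = x$transcript_id,
    gene_id = x$gene_id,
    chrom = x$chrom,
    strand = x$strand,
    intron_start = x$end,
    intron_end = x$next_start,
    donor_pos = ifelse(x$strand == "+", x$end, x$next_start - 1L),
    acceptor_pos = ifelse(x$strand == "+", x$next_start - 1L, x$end)
  )
}

#' Convert read counts to FPKM
#'
#' FPKM = 1e9 * count / (library_size * transcript_length).
#'
#' @param read_count Non-negative read counts (vectorized).
#' @param transcript_length_nt Transcript lengths in nucleotides (> 0).
#' @param library_size Total mapped reads in the library (> 0).
#' @return Numeric FPKM values.
#' @export
counts_to_fpkm <- function(read_count, transcript_length_nt, library_size) {
  if (any(transcript_length_nt <= 0)) ss_abort("transcript length must be > 0")
  if (any(library_size <= 0)) ss_abort("library size must be > 0")
  1e9 * read_count / (as.numeric(library_size) * transcript_length_nt)
}

#' Export junctions as BED6
#'
#' @param junctions Junction tibble from [introns_of()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
junctions_to_bed <- function(junctions, path) {
  assert_cols(junctions, c("chrom", "intron_start", "intron_end", "strand"))
  bed <- tibble(
    chrom = junctions$chrom,
    chromStart = junctions$intron_start,
    chromEnd = junctions$intron_end,
    name = sprintf("%s:%d-%d:%s", junctions$chrom, junctions$intron_start,
                   junctions$intron_end, junctions$strand),
    score = 0L,
    strand = junctions$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] named by the first word of each
#'   header.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Spliced transcript sequences
#'
#' Concatenates exon sequences in transcription order (reverse-complemented
#' for `-` strand transcripts).
#'
#' @param exons Exon tibble.
#' @param genome A named [Biostrings::DNAStringSet].
#' @return A tibble with `transcript_id` and `seq` (character).
#' @export
transcript_seq <- function(exons, genome) {
  exons <- validate_exons(exons)
  exons %>%
    group_by(.data$transcript_id) %>%
    summarise(seq = splice_seq(first(.data$chrom), .data$start, .data$end,
                               first(.data$strand), genome),
              .groups = "drop")
}

splice_seq <- function(chrom, starts, ends, strand, genome) {
  if (!chrom %in% names(genome)) ss_abort(sprintf("chrom %s not in genome", chrom))
  pieces <- substring(as.character(genome[[chrom]]), starts + 1L, ends)
  s <- paste(pieces, collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}
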