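rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("SAST anchors cap at 300 nt and truncate at gene boundaries", {
  set.seed(3)
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_dna(3000)))
  ev <- tibble::tibble(event_id = "e1", gene_id = "g1", chrom = "chr1",
                       strand = "+", event_type = "IntronR",
                       junctions = "1000-1200")
  gb_wide <- tibble::tibble(gene_id = "g1", start = 200L, end = 2500L)
  s <- make_sast(ev, genome, gb_wide)
  expect_equal(nchar(s$upstream), 300)
  expect_equal(nchar(s$downstream), 300)

  gb_tight <- tibble::tibble(gene_id = "g1", start = 880L, end = 1350L)
  s2 <- make_sast(ev, genome, gb_tight)
  expect_equal(nchar(s2$upstream), 120)
  expect_equal(nchar(s2$downstream), 150)

  # a junction flush against the gene edge has no anchor
  gb_bad <- tibble::tibble(gene_id = "g1", start = 1000L, end = 1350L)
  expect_error(make_sast(ev, genome, gb_bad), "empty anchor")
})

test_that("minus-strand anchors are the reverse complement in transcription order", {
  set.seed(4)
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_dna(3000)))
  base <- tibble::tibble(event_id = "e1", gene_id = "g1", chrom = "chr1",
                         event_type = "IntronR", junctions = "1000-1200")
  gb <- tibble::tibble(gene_id = "g1", start = 200L, end = 2500L)
  sp <- make_sast(dplyr::mutate(base, strand = "+"), genome, gb)
  sm <- make_sast(dplyr::mutate(base, strand = "-"), genome, gb)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(sm$upstream, rc(sp$downstream))
  expect_equal(sm$downstream, rc(sp$upstream))
})

test_that("translated alignment scores are symmetric with sane E-values", {
  set.seed(5)
  a <- rand_dna(150)
  self <- translated_align(a, a)
  expect_lt(self$evalue, 1e-5)
  b <- rand_dna(150)
  ab <- translated_align(a, b)
  ba <- translated_align(b, a)
  expect_equal(ab$score, ba$score)
  # E follows the stated Karlin-Altschul form
  expect_equal(ab$evalue, 0.041 * 150 * 150 * exp(-0.267 * ab$score))
  # unrelated anchors rarely reach the threshold
  es <- replicate(40, translated_align(rand_dna(150), rand_dna(150))$evalue)
  expect_gte(mean(es > 1e-5), 0.95)
  expect_error(translated_align("AC", a), ">= 3 nt")
})

test_that("triplet classification recovers planted categories", {
  tri <- simulate_triplets(n_triplets = 24, divergence = 0.02, seed = 9)
  sasts <- dplyr::bind_rows(lapply(names(tri$exons), function(g) {
    ev <- detect_events(tri$exons[[g]])
    if (nrow(ev) == 0) return(NULL)
    gb <- gene_loci(tri$exons[[g]])
    dplyr::mutate(make_sast(ev, tri$genomes[[g]], gb), genome = g)
  }))
  calls <- classify_triplet_events(tri$triplets, sasts)
  j <- dplyr::inner_join(tri$truth, calls, by = "triplet_id",
                         suffix = c("_true", "_called"))
  expect_equal(nrow(j), nrow(tri$truth))
  expect_true(all(j$category_true == j$category_called))
  expect_true(all(j$event_type_true == j$event_type_called))
})

test_that("deleted events produce no SASTs and exact copies classify perfectly", {
  tri <- simulate_triplets(n_triplets = 10, divergence = 0, seed = 15)
  # members lacking the alternative isoform yield no events at all
  for (g in names(tri$exons)) {
    ev <- detect_events(tri$exons[[g]])
    n_tx <- tri$exons[[g]] %>%
      dplyr::distinct(gene_id, transcript_id) %>%
      dplyr::count(gene_id)
    expect_setequal(unique(ev$gene_id), n_tx$gene_id[n_tx$n >= 2])
  }
  sasts <- dplyr::bind_rows(lapply(names(tri$exons), function(g) {
    ev <- detect_events(tri$exons[[g]])
    if (nrow(ev) == 0) return(NULL)
    dplyr::mutate(make_sast(ev, tri$genomes[[g]], gene_loci(tri$exons[[g]])),
                  genome = g)
  }))
  calls <- classify_triplet_events(tri$triplets, sasts)
  j <- dplyr::inner_join(tri$truth, calls, by = "triplet_id",
                         suffix = c("_true", "_called"))
  expect_equal(nrow(j), 10)
  expect_true(all(j$category_true == j$category_called))
})

test_that("swapping the maize subgenome labels swaps categories 2 and 3", {
  tri <- simulate_triplets(n_triplets = 16, divergence = 0.02, seed = 25)
  sasts <- dplyr::bind_rows(lapply(names(tri$exons), function(g) {
    ev <- detect_events(tri$exons[[g]])
    if (nrow(ev) == 0) return(NULL)
    dplyr::mutate(make_sast(ev, tri$genomes[[g]], gene_loci(tri$exons[[g]])),
                  genome = g)
  }))
  calls <- classify_triplet_events(tri$triplets, sasts)
  swapped_sasts <- sasts %>%
    dplyr::mutate(genome = dplyr::recode(genome, maize1 = "maize2",
                                         maize2 = "maize1"))
  swapped_triplets <- tri$triplets %>%
    dplyr::rename(maize1_gene = maize2_gene, maize2_gene = maize1_gene)
  calls_sw <- classify_triplet_events(swapped_triplets, swapped_sasts)
  m <- dplyr::inner_join(calls, calls_sw, by = c("triplet_id", "event_type"),
                         suffix = c("", "_sw"))
  expect_equal(nrow(m), nrow(calls))
  remap <- c(`1` = 1L, `2` = 3L, `3` = 2L, `4` = 4L)
  expect_equal(m$category_sw, unname(remap[as.character(m$category)]))
})

test_that("conservation summaries count clusters, events, and genes", {
  calls <- tibble::tibble(triplet_id = "trip1", event_type = "IntronR",
                          category = 1L, e_m1_s = 1e-10, e_m2_s = 1e-10,
                          e_m1_m2 = 1e-10, n_member_events = 3L,
                          genes = "gA,gB,gC")
  s <- summarize_conservation(calls)
  expect_equal(s$clusters, 1L)
  expect_equal(s$events, 3L)
  expect_equal(s$genes, 3L)
  empty <- summarize_conservation(calls[0, ])
  expect_equal(nrow(empty), 0)
})
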