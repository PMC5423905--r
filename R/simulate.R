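#' Simulate a genome with multi-isoform gene models and planted AS events
#'
#' Generates random nucleotide chromosomes carrying genes of 2-12 exons
#' (exon 50-400 nt, intron 60-3000 nt by default). Each gene has one
#' canonical isoform (all exons) and 0-3 alternative isoforms, each
#' carrying exactly one planted event with type drawn from
#' `event_props` (defaults follow the rank order observed in plant
#' transcriptomes: intron retention most common, exon skipping rarest).
#' Each alternative isoform perturbs a distinct intron/exon of the gene,
#' so planted events never collide.
#'
#' @param n_genes Number of genes (default 30).
#' @param n_chroms Number of chromosomes genes are spread over (default 2).
#' @param seed Integer seed; generation is a pure function of the
#'   arguments.
#' @param exon_count_range,exon_range,intron_range,intergenic_range
#'   Structural ranges (nt).
#' @param n_alt_range Range of alternative isoforms per gene.
#' @param event_props Named sampling weights over the five event types.
#' @return List: `genome` ([Biostrings::DNAStringSet]), `exons` (tibble),
#'   `truth` (tibble: `gene_id`, `transcript_id`, `event_type`, `chrom`,
#'   `strand`, `affected_start`, `affected_end`), `params`.
#' @export
simulate_genome <- function(n_genes = 30, n_chroms = 2, seed = 1,
                            exon_count_range = c(2, 12),
                            exon_range = c(50, 400),
                            intron_range = c(60, 3000),
                            intergenic_range = c(500, 2000),
                            n_alt_range = c(0, 3),
                            event_props = c(IntronR = 0.47, AltA = 0.20,
                                            AltD = 0.13, ExonS = 0.05,
                                            AltTE = 0.15)) {
  params <- as.list(environment())
  withr::with_seed(seed, {
    cursors <- rep(0L, n_chroms)
    exons <- list(); truth <- list()
    for (g in seq_len(n_genes)) {
      chrom_i <- (g - 1L) %% n_chroms + 1L
      chrom <- sprintf("chr%d", chrom_i)
      gene_id <- sprintf("g%04d", g)
      start0 <- cursors[chrom_i] +
        sample(intergenic_range[1]:intergenic_range[2], 1)
      gene <- build_gene(gene_id, chrom, start0, exon_count_range,
                         exon_range, intron_range, n_alt_range, event_props)
      exons[[g]] <- gene$exons
      truth[[g]] <- gene$truth
      cursors[chrom_i] <- max(gene$exons$end)
    }
    exons <- bind_rows(exons)
    truth <- bind_rows(truth)
    lens <- exons %>% group_by(.data$chrom) %>%
      summarise(len = max(.data$end) + 1000L, .groups = "drop")
    genome <- Biostrings::DNAStringSet(vapply(lens$len, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)))
    names(genome) <- lens$chrom
    list(genome = genome, exons = validate_exons(exons), truth = truth,
         params = params)
  })
}

# one gene: canonical isoform plus alternative isoforms with one planted
# event each, each on a distinct structural element
build_gene <- function(gene_id, chrom, start0, exon_count_range, exon_range,
                       intron_range, n_alt_range, event_props) {
  n_ex <- sample(exon_count_range[1]:exon_count_range[2], 1)
  ex_len <- sample(exon_range[1]:exon_range[2], n_ex, replace = TRUE)
  in_len <- if (n_ex > 1) {
    sample(intron_range[1]:intron_range[2], n_ex - 1, replace = TRUE)
  } else {
    integer(0)
  }
  starts <- start0 + cumsum(c(0L, head(ex_len, -1) + in_len))
  ends <- starts + ex_len
  strand <- sample(c("+", "-"), 1)
  canonical <- tibble(
    transcript_id = sprintf("%s.t1", gene_id), gene_id = gene_id,
    chrom = chrom, start = starts, end = ends, strand = strand)
  n_alt <- sample(n_alt_range[1]:n_alt_range[2], 1)
  free_introns <- seq_len(n_ex - 1)
  free_internal <- if (n_ex >= 3) 2:(n_ex - 1) else integer(0)
  terminal_free <- n_ex >= 2
  alt_exons <- list(); truth <- list()
  k <- 0L
  while (k < n_alt) {
    type <- sample(names(event_props), 1, prob = event_props)
    feasible <- switch(type,
      IntronR = length(free_introns) > 0,
      AltA = length(free_introns) > 0,
      AltD = length(free_introns) > 0,
      ExonS = length(free_internal) > 0,
      AltTE = terminal_free)
    if (!feasible) {
      # no structural element left for any type -> stop planting
      if (length(free_introns) == 0 && length(free_internal) == 0 &&
          !terminal_free) break
      next
    }
    k <- k + 1L
    tid <- sprintf("%s.t%d", gene_id, k + 1L)
    planted <- plant_event(type, canonical, tid, free_introns,
                           free_internal, exon_range, intron_range)
    if (is.null(planted)) { k <- k - 1L; next }
    alt_exons[[k]] <- planted$exons
    truth[[k]] <- tibble(gene_id = gene_id, transcript_id = tid,
                         event_type = type, chrom = chrom, strand = strand,
                         affected_start = planted$affected[1],
                         affected_end = planted$affected[2])
    free_introns <- setdiff(free_introns, planted$used_intron)
    free_internal <- setdiff(free_internal, planted$used_exon)
    if (type == "AltTE") terminal_free <- FALSE
    # a skipped exon consumes its flanking introns; a perturbed intron
    # consumes its flanking internal exons as ExonS targets
    if (type == "ExonS") {
      free_introns <- setdiff(free_introns,
                              c(planted$used_exon - 1, planted$used_exon))
    }
    if (type %in% c("IntronR", "AltA", "AltD")) {
      free_internal <- setdiff(free_internal,
                               c(planted$used_intron, planted$used_intron + 1))
    }
  }
  list(exons = bind_rows(canonical, bind_rows(alt_exons)),
       truth = bind_rows(truth))
}

plant_event <- function(type, canonical, tid, free_introns, free_internal,
                        exon_range, intron_range) {
  ex <- canonical
  n_ex <- nrow(ex)
  strand <- ex$strand[1]
  mk <- function(starts, ends) {
    tibble(transcript_id = tid, gene_id = ex$gene_id[1], chrom = ex$chrom[1],
           start = as.integer(starts), end = as.integer(ends),
           strand = strand)
  }
  if (type == "IntronR") {
    i <- if (length(free_introns) == 1) free_introns else sample(free_introns, 1)
    starts <- ex$start[-(i + 1)]
    ends <- ex$end[-i]
    list(exons = mk(starts, ends),
         affected = c(ex$end[i], ex$start[i + 1]),
         used_intron = i, used_exon = integer(0))
  } else if (type == "ExonS") {
    i <- if (length(free_internal) == 1) free_internal else sample(free_internal, 1)
    list(exons = mk(ex$start[-i], ex$end[-i]),
         affected = c(ex$start[i], ex$end[i]),
         used_intron = integer(0), used_exon = i)
  } else if (type %in% c("AltA", "AltD")) {
    i <- if (length(free_introns) == 1) free_introns else sample(free_introns, 1)
    exon_lo <- ex$end[i] - ex$start[i]        # exon upstream of intron i
    exon_hi <- ex$end[i + 1] - ex$start[i + 1]
    intron_len <- ex$start[i + 1] - ex$end[i]
    delta_max <- min(45L, exon_lo - 20L, exon_hi - 20L, intron_len - 20L)
    if (delta_max < 6) return(NULL)
    delta <- sample(6:delta_max, 1) * sample(c(-1L, 1L), 1)
    # AltA moves the acceptor, AltD the donor; which genomic end of the
    # intron that is depends on strand
    move_end <- (type == "AltA") == (strand == "+")
    starts <- ex$start; ends <- ex$end
    if (move_end) {
      new_acc <- ex$start[i + 1] + delta
      starts[i + 1] <- new_acc
      affected <- sort(c(ex$start[i + 1], new_acc))
    } else {
      new_don <- ex$end[i] + delta
      ends[i] <- new_don
      affected <- sort(c(ex$end[i], new_don))
    }
    list(exons = mk(starts, ends), affected = affected,
         used_intron = i, used_exon = integer(0))
  } else {  # AltTE: divergent terminal exon at the genomic right end
    if (n_ex < 2) return(NULL)
    shared_end <- ex$end[n_ex - 1]
    delta <- sample(9:30, 1)
    if (shared_end - delta - ex$start[n_ex - 1] < 20) return(NULL)
    gap <- sample(100:500, 1)
    novel_len <- sample(exon_range[1]:exon_range[2], 1)
    novel_start <- ex$end[n_ex] + gap
    starts <- c(ex$start[seq_len(n_ex - 1)], novel_start)
    ends <- c(ex$end[seq_len(n_ex - 2)], shared_end - delta,
              novel_start + novel_len)
    list(exons = mk(starts, ends),
         affected = c(novel_start, novel_start + novel_len),
         used_intron = n_ex - 1, used_exon = integer(0))
  }
}

#' Simulate isoform FPKM tables across developmental stages
#'
#' Emulates staged expression with planted splicing-ratio trajectories:
#' for genes with a single alternative isoform carrying an IntronR or
#' ExonS event, the event's ratio either stays flat or rises by exactly
#' `delta` from the first to the last stage along a normalized logistic
#' curve. Gene-level expression is log-normal; rising-retention genes
#' optionally decay in expression across stages (the negative
#' IRR-expression coupling seen in developing seed). With `noise_sd = 0`
#' the realized ratios equal the planted ratios exactly.
#'
#' @param sim Output of [simulate_genome()].
#' @param stages Numeric stage labels (default 8 stages over days 0-38).
#' @param n_reps Replicates per stage (default 3).
#' @param rising_fraction Fraction of eligible events given a rising
#'   trajectory (default 0.5).
#' @param delta Planted end-minus-start ratio change for rising events
#'   (default 0.3).
#' @param noise_sd Log-normal multiplicative noise sd (default 0).
#' @param base_meanlog,base_sdlog Gene base-expression log-normal
#'   parameters.
#' @param expr_decay Per-stage-index log-expression decay applied to
#'   rising-trajectory genes (default 0.15).
#' @param seed Integer seed.
#' @return List: `fpkm` (long tibble: `transcript_id`, `sample_id`,
#'   `stage`, `rep`, `fpkm`), `ratio_truth` (planted per-stage ratios per
#'   event, keyed by gene/type/affected interval), `samples` (sample
#'   sheet).
#' @export
simulate_expression <- function(sim, stages = c(0, 6, 12, 18, 24, 30, 34, 38),
                                n_reps = 3, rising_fraction = 0.5,
                                delta = 0.3, noise_sd = 0,
                                base_meanlog = log(20), base_sdlog = 1,
                                expr_decay = 0.15, seed = 1) {
  truth <- sim$truth
  n_alt_per_gene <- truth %>% dplyr::count(.data$gene_id, name = "n_alt")
  eligible <- truth %>%
    left_join(n_alt_per_gene, by = "gene_id") %>%
    filter(.data$n_alt == 1, .data$event_type %in% c("IntronR", "ExonS"))
  all_tx <- unique(sim$exons$transcript_id)
  genes <- unique(sim$exons$gene_id)
  withr::with_seed(seed, {
    base <- setNames(exp(rnorm(length(genes), base_meanlog, base_sdlog)),
                     genes)
    rising <- stats::rbinom(nrow(eligible), 1, rising_fraction) == 1
    r0 <- runif(nrow(eligible), 0.10, 0.55)
    flat_r <- runif(nrow(eligible), 0.20, 0.80)
    x <- seq(0, 1, length.out = length(stages))
    lg <- function(x) stats::plogis(8 * (x - 0.5))
    curve01 <- (lg(x) - lg(0)) / (lg(1) - lg(0))
    ratio_truth <- purrr::map(seq_len(nrow(eligible)), function(i) {
      r <- if (rising[i]) r0[i] + delta * curve01 else rep(flat_r[i],
                                                           length(stages))
      tibble(gene_id = eligible$gene_id[i],
             transcript_id = eligible$transcript_id[i],
             event_type = eligible$event_type[i],
             affected_start = eligible$affected_start[i],
             affected_end = eligible$affected_end[i],
             trajectory = if (rising[i]) "rising" else "flat",
             stage = stages, on_ratio = r)
    }) %>% bind_rows()
    samples <- tidyr::expand_grid(stage = stages, rep = seq_len(n_reps)) %>%
      mutate(sample_id = sprintf("d%02d_r%d", .data$stage, .data$rep))
    tx_info <- sim$exons %>% distinct(.data$transcript_id, .data$gene_id)
    fpkm <- purrr::map(seq_len(nrow(samples)), function(si) {
      st <- samples$stage[si]
      si_idx <- match(st, stages)
      per_gene <- purrr::map(genes, function(gid) {
        tx <- tx_info$transcript_id[tx_info$gene_id == gid]
        el <- which(eligible$gene_id == gid)
        gene_base <- base[[gid]]
        if (length(el) == 1) {
          if (rising[el]) gene_base <- gene_base * exp(-expr_decay * (si_idx - 1))
          r <- ratio_truth$on_ratio[ratio_truth$gene_id == gid &
                                      ratio_truth$stage == st][1]
          alt <- eligible$transcript_id[el]
          # "on" side: the retention isoform for IntronR (the alternative),
          # the exon-including isoform for ExonS (the canonical)
          on_is_alt <- eligible$event_type[el] == "IntronR"
          frac <- setNames(rep(0, length(tx)), tx)
          frac[alt] <- if (on_is_alt) r else 1 - r
          frac[setdiff(tx, alt)] <- (1 - frac[alt]) / (length(tx) - 1)
        } else {
          w <- stats::rgamma(length(tx), shape = 2)
          frac <- setNames(w / sum(w), tx)
        }
        tibble(transcript_id = tx, fpkm = gene_base * unname(frac))
      }) %>% bind_rows()
      per_gene %>% mutate(sample_id = samples$sample_id[si], stage = st,
                          rep = samples$rep[si])
    }) %>% bind_rows()
    if (noise_sd > 0) {
      fpkm$fpkm <- fpkm$fpkm * exp(rnorm(nrow(fpkm), 0, noise_sd))
    }
    list(fpkm = fpkm %>% select("transcript_id", "sample_id", "stage",
                                "rep", "fpkm"),
         ratio_truth = ratio_truth, samples = samples)
  })
}

#' Simulate junction read evidence and intron coverage
#'
#' Genuine junctions receive spanning reads multinomially spread over
#' alignment offsets (high entropy); artifact junctions pile all reads at
#' a single offset (entropy 0). Retained introns receive Poisson per-base
#' coverage at `retained_cov` and boundary/spliced read counts consistent
#' with a planted retention fraction; non-retained introns get sparse
#' coverage and near-zero retention.
#'
#' @param sim Output of [simulate_genome()] (its canonical junctions are
#'   the genuine junction set).
#' @param depth Expected spanning reads per junction (default 50).
#' @param n_offsets Distinct possible alignment offsets (default 45).
#' @param n_artifacts Number of artifact junctions to add (default 20).
#' @param retained_cov Per-base coverage of retained introns (default 20).
#' @param retained_ir Planted retention fraction of retained introns
#'   (default 0.3).
#' @param null_cov,null_ir Coverage / retention for non-retained introns.
#' @param max_intron_eval Introns longer than this are truncated for the
#'   per-base vector (default 2000).
#' @param seed Integer seed.
#' @return List: `evidence` (tibble `junction_id`, `offset`, `count`,
#'   `true_junction`), `intron_support` (tibble `junction_id`, `retained`,
#'   `boundary_reads`, `spliced_reads`, `depth` list-column).
#' @export
simulate_junction_evidence <- function(sim, depth = 50, n_offsets = 45,
                                       n_artifacts = 20, retained_cov = 20,
                                       retained_ir = 0.3, null_cov = 1,
                                       null_ir = 0.02,
                                       max_intron_eval = 2000, seed = 1) {
  canon <- gene_loci(sim$exons)
  jx <- introns_of(sim$exons %>%
                     semi_join(canon %>%
                                 select(gene_id = "gene_id",
                                        transcript_id = "canonical_id"),
                               by = c("gene_id", "transcript_id"))) %>%
    mutate(junction_id = sprintf("%s:%d-%d:%s", .data$chrom,
                                 .data$intron_start, .data$intron_end,
                                 .data$strand))
  retained_keys <- sim$truth %>%
    filter(.data$event_type == "IntronR") %>%
    mutate(junction_id = sprintf("%s:%d-%d:%s", .data$chrom,
                                 .data$affected_start, .data$affected_end,
                                 .data$strand)) %>%
    pull(.data$junction_id)
  withr::with_seed(seed, {
    ev_true <- purrr::map(seq_len(nrow(jx)), function(i) {
      total <- rpois(1, depth) + 1L
      counts <- as.integer(stats::rmultinom(1, total, rep(1, n_offsets)))
      keep <- counts > 0
      tibble(junction_id = jx$junction_id[i],
             offset = which(keep), count = counts[keep],
             true_junction = TRUE)
    }) %>% bind_rows()
    ev_art <- purrr::map(seq_len(n_artifacts), function(i) {
      tibble(junction_id = sprintf("artifact%03d", i),
             offset = sample(n_offsets, 1), count = rpois(1, depth) + 1L,
             true_junction = FALSE)
    }) %>% bind_rows()
    support <- purrr::map(seq_len(nrow(jx)), function(i) {
      retained <- jx$junction_id[i] %in% retained_keys
      len <- min(jx$intron_end[i] - jx$intron_start[i], max_intron_eval)
      cov <- if (retained) retained_cov else null_cov
      q <- if (retained) retained_ir else null_ir
      total <- rpois(1, depth) + 1L
      b <- rbinom(1, total, q)
      tibble(junction_id = jx$junction_id[i], retained = retained,
             boundary_reads = b, spliced_reads = total - b,
             depth = list(rpois(len, cov)))
    }) %>% bind_rows()
    list(evidence = bind_rows(ev_true, ev_art), intron_support = support)
  })
}

# beta-binomial draws with intraclass correlation rho
rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- rbeta(n, a, b)
  rbinom(n, size, p)
}

#' Simulate a biparental RIL panel with junction counts
#'
#' Genotypes are mosaic segments of the two parents (B and M) generated by
#' a Markov switching process along equal-sized marker segments. Junction
#' spanning counts follow a beta-binomial around a logistic model of the
#' splicing frequency, with planted cis/trans/interaction log-odds
#' effects. SNPs are planted inside the 12-bp splice-site windows of
#' designated junctions at an elevated rate to emulate cis polymorphism
#' enrichment.
#'
#' @param n_lines Number of RILs (default 105, a standard intermated
#'   biparental panel size).
#' @param n_chroms,chrom_length,markers_per_chrom Marker map geometry.
#' @param n_junctions Junctions to simulate (default 20).
#' @param effects Optional tibble of planted effects: `junction_id`,
#'   `beta_cis`, `beta_trans`, `beta_inter`, `trans_marker` (NA where
#'   unused). Junctions absent from it are null.
#' @param rho Beta-binomial intraclass correlation (default 0.05).
#' @param depth Expected gene reads per line (default 50).
#' @param baseline Baseline log-odds of the splicing frequency
#'   (default `qlogis(0.2)`).
#' @param switch_prob Genotype switch probability between adjacent
#'   segments (default 0.1).
#' @param missing_rate Fraction of genotype calls set missing (default 0).
#' @param snp_rate_sig,snp_rate_null Per-junction probability of planting
#'   a SNP inside the splice-site windows for effect vs null junctions.
#' @param seed Integer seed.
#' @return List: `panel` (list of `markers`, `genotypes`),
#'   `junction_meta`, `junctions` (with intron coordinates/strand),
#'   `counts` (long `junction_id`, `line_id`, `y`, `r`), `snps`,
#'   `chrom_lengths`, `truth`.
#' @export
simulate_ril_panel <- function(n_lines = 105, n_chroms = 2,
                               chrom_length = 5e7, markers_per_chrom = 20,
                               n_junctions = 20, effects = NULL,
                               rho = 0.05, depth = 50,
                               baseline = qlogis(0.2), switch_prob = 0.1,
                               missing_rate = 0, snp_rate_sig = 0.5,
                               snp_rate_null = 0.03, seed = 1) {
  if (is.null(effects)) {
    effects <- tibble(junction_id = character(), beta_cis = double(),
                      beta_trans = double(), beta_inter = double(),
                      trans_marker = character())
  }
  withr::with_seed(seed, {
    seg_len <- chrom_length / markers_per_chrom
    markers <- tidyr::expand_grid(chrom = sprintf("chr%d", seq_len(n_chroms)),
                                  k = seq_len(markers_per_chrom)) %>%
      mutate(marker_id = sprintf("%s_m%02d", .data$chrom, .data$k),
             start = as.integer((.data$k - 1) * seg_len),
             end = as.integer(.data$k * seg_len)) %>%
      select("marker_id", "chrom", "start", "end")
    line_ids <- sprintf("RIL%03d", seq_len(n_lines))
    # Markov mosaic per line: initial parent 50/50, then switch between
    # adjacent segments with switch_prob; vectorized over lines
    genotypes <- purrr::map(sprintf("chr%d", seq_len(n_chroms)), function(ch) {
      init <- rbinom(n_lines, 1, 0.5)
      state <- if (markers_per_chrom == 1) {
        matrix(init, ncol = 1)
      } else {
        switches <- matrix(
          runif(n_lines * (markers_per_chrom - 1)) < switch_prob,
          nrow = n_lines)
        (init + cbind(0L, t(apply(switches, 1, cumsum)))) %% 2L
      }
      tibble(line_id = rep(line_ids, markers_per_chrom),
             marker_id = rep(markers$marker_id[markers$chrom == ch],
                             each = n_lines),
             genotype = c("B", "M")[as.vector(state) + 1L])
    }) %>% bind_rows() %>% arrange(.data$line_id)
    if (missing_rate > 0) {
      drop <- runif(nrow(genotypes)) < missing_rate
      genotypes$genotype[drop] <- NA_character_
    }
    junctions <- tibble(
      junction_id = sprintf("jx%03d", seq_len(n_junctions)),
      chrom = sample(sprintf("chr%d", seq_len(n_chroms)), n_junctions,
                     replace = TRUE),
      intron_start = as.integer(runif(n_junctions, 1e4, chrom_length - 1e4)),
      strand = sample(c("+", "-"), n_junctions, replace = TRUE)) %>%
      mutate(intron_end = .data$intron_start +
               as.integer(sample(60:3000, n_junctions, replace = TRUE)),
             pos = .data$intron_start)
    junction_meta <- junctions %>% select("junction_id", "chrom", "pos")
    cis_ids <- cis_marker_of(junction_meta,
                             markers)
    counts <- purrr::map(seq_len(n_junctions), function(i) {
      jid <- junctions$junction_id[i]
      eff <- effects %>% filter(.data$junction_id == jid)
      val <- function(x) if (nrow(eff) == 1 && !is.na(x)) x else 0
      g_cis <- genotype_vector(genotypes, cis_ids[i], line_ids)
      g_tr <- if (nrow(eff) == 1 && !is.na(eff$trans_marker)) {
        genotype_vector(genotypes, eff$trans_marker, line_ids)
      } else {
        rep(0, n_lines)
      }
      eta <- baseline +
        val(eff$beta_cis[1]) * dplyr::coalesce(g_cis, 0) +
        val(eff$beta_trans[1]) * dplyr::coalesce(g_tr, 0) +
        val(eff$beta_inter[1]) * dplyr::coalesce(g_cis * g_tr, 0)
      n_tot <- rpois(n_lines, depth) + 1L
      y <- rbetabinom(n_lines, n_tot, plogis(eta), rho)
      tibble(junction_id = jid, line_id = line_ids, y = y, r = n_tot - y)
    }) %>% bind_rows()
    wins <- splice_site_windows(junctions)
    sig_ids <- effects$junction_id
    snps <- purrr::map(seq_len(n_junctions), function(i) {
      p <- if (junctions$junction_id[i] %in% sig_ids) snp_rate_sig else snp_rate_null
      if (runif(1) >= p) return(NULL)
      w <- wins[i, ]
      pos <- sample(c(w$donor_win_start:(w$donor_win_end - 1L),
                      w$acceptor_win_start:(w$acceptor_win_end - 1L)), 1)
      tibble(chrom = junctions$chrom[i], pos = pos)
    }) %>% bind_rows()
    n_bg <- n_chroms * 50L
    snps <- bind_rows(snps, tibble(
      chrom = sample(sprintf("chr%d", seq_len(n_chroms)), n_bg, replace = TRUE),
      pos = as.integer(runif(n_bg, 1, chrom_length))))
    list(panel = list(markers = markers, genotypes = genotypes),
         junction_meta = junction_meta, junctions = junctions,
         counts = counts, snps = snps,
         chrom_lengths = setNames(rep(chrom_length, n_chroms),
                                  sprintf("chr%d", seq_len(n_chroms))),
         truth = list(effects = effects, rho = rho, depth = depth,
                      baseline = baseline))
  })
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0) {
    # substitute each hit with one of the three other bases, vectorized
    alt <- matrix(c("C", "G", "T",   # A ->
                    "A", "G", "T",   # C ->
                    "A", "C", "T",   # G ->
                    "A", "C", "G"),  # T ->
                  nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    chars[hit] <- alt[cbind(match(chars[hit], rownames(alt)),
                            sample.int(3, length(hit), replace = TRUE))]
  }
  paste(chars, collapse = "")
}

#' Simulate diverged ortholog triplets with planted conservation categories
#'
#' For each triplet an ancestral gene with one planted AS event is
#' generated and copied to three genomes (maize subgenome1, subgenome2,
#' sorghum). Each copy accumulates independent point substitutions at the
#' given per-copy rate. The planted conservation category decides which
#' members keep the alternative isoform: category 1 keeps all three,
#' category 2 deletes it from subgenome2, category 3 from subgenome1,
#' category 4 from sorghum.
#'
#' @param n_triplets Number of triplets (default 200).
#' @param divergence Per-copy substitution rate (default 0.02).
#' @param category_mix Sampling weights over categories 1-4.
#' @param event_props Event-type weights (uniform by default so all five
#'   types are exercised).
#' @param seed Integer seed.
#' @return List: `genomes` (named list of DNAStringSet), `exons` (named
#'   list of exon tibbles; gene ids carry a `_m1`/`_m2`/`_s` suffix),
#'   `triplets` (tibble with gene ids and eligibility flags), `truth`
#'   (tibble `triplet_id`, `category`, `event_type`), `params`.
#' @export
simulate_triplets <- function(n_triplets = 200, divergence = 0.02,
                              category_mix = c(0.25, 0.25, 0.25, 0.25),
                              event_props = c(IntronR = 0.2, AltA = 0.2,
                                              AltD = 0.2, ExonS = 0.2,
                                              AltTE = 0.2), seed = 1) {
  params <- as.list(environment())
  withr::with_seed(seed, {
    cursor <- 0L
    exons_all <- list(maize1 = list(), maize2 = list(), sorghum = list())
    triplets <- list(); truth <- list()
    suffix <- c(maize1 = "_m1", maize2 = "_m2", sorghum = "_s")
    for (t in seq_len(n_triplets)) {
      start0 <- cursor + 400L
      gene_id <- sprintf("tg%04d", t)
      gene <- NULL
      while (is.null(gene) || nrow(gene$truth) != 1) {
        gene <- build_gene(gene_id, "chr1", start0, c(3, 6), c(80, 250),
                           c(60, 300), c(1, 1), event_props)
      }
      cursor <- max(gene$exons$end)
      category <- sample(1:4, 1, prob = category_mix)
      drop_member <- switch(category, NA, "maize2", "maize1", "sorghum")
      for (g in names(suffix)) {
        gx <- gene$exons %>%
          mutate(gene_id = paste0(.data$gene_id, suffix[[g]]),
                 transcript_id = paste0(.data$transcript_id, suffix[[g]]))
        if (!is.na(drop_member) && g == drop_member) {
          alt_tid <- paste0(gene$truth$transcript_id, suffix[[g]])
          gx <- gx %>% filter(.data$transcript_id != alt_tid)
        }
        exons_all[[g]][[t]] <- gx
      }
      triplets[[t]] <- tibble(
        triplet_id = sprintf("trip%04d", t),
        maize1_gene = paste0(gene_id, "_m1"),
        maize2_gene = paste0(gene_id, "_m2"),
        sorghum_gene = paste0(gene_id, "_s"),
        multi_exon = TRUE, expressed = TRUE)
      truth[[t]] <- tibble(triplet_id = sprintf("trip%04d", t),
                           category = category,
                           event_type = gene$truth$event_type)
      cursor <- cursor + 400L
    }
    # one shared ancestral chromosome; gene coordinates are identical in
    # all three genomes because copies differ only by substitutions
    anc <- paste(sample(c("A", "C", "G", "T"), cursor + 1000L,
                        replace = TRUE), collapse = "")
    genomes <- lapply(setNames(names(suffix), names(suffix)), function(g) {
      s <- Biostrings::DNAStringSet(mutate_seq(anc, divergence))
      names(s) <- "chr1"
      s
    })
    list(genomes = genomes,
         exons = lapply(exons_all, bind_rows),
         triplets = bind_rows(triplets), truth = bind_rows(truth),
         params = params)
  })
}
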