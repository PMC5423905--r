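#' Default pipeline configuration
#'
#' All tunable thresholds of the analysis with their standard defaults:
#' junction entropy > 2 bits; retained-intron coverage 10x over 90% of the
#' intron with retention >= 10%; isoform acceptance at FPKM >= 1 and >= 5%
#' isoform fraction; ratio-matrix bounds 0.05-0.95 at FPKM >= 1;
#' stage-contrast selection at delta > 0.15; differential-splicing
#' post-filter at FPKM >= 5; PAV at > 2 / < 0.1 FPKM; sQTL junction
#' eligibility at 20 total / 5 mean spanning reads; cis FDR 5% with a
#' two-fold odds filter; 100 merged regions per chromosome for the trans
#' cutoff; conservation alignment at E <= 1e-5 (1e-2 below 100-nt
#' anchors), 300-nt anchors, 30-nt minimum aligned span.
#'
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_entropy = 2,
    ir_min_depth = 10, ir_min_covered = 0.9, ir_min_percent = 10,
    min_fpkm = 1, min_fraction = 0.05,
    ratio_bounds = c(0.05, 0.95),
    delta_threshold = 0.15,
    diff_min_fpkm = 5,
    pav_high = 2, pav_low = 0.1,
    min_spanning = 20, min_mean_per_line = 5,
    fdr = 0.05, fold = 2, regions_per_chrom = 100,
    e_max = 1e-5, e_max_short = 1e-2, short_len = 100,
    max_anchor = 300, min_aligned = 30,
    log_eps = 1e-6,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    ss_abort(sprintf("unknown configuration parameter(s): %s",
                     paste(unknown, collapse = ", ")))
  }
  for (nm in names(over)) {
    if (!is.numeric(over[[nm]]) || length(over[[nm]]) != length(cfg[[nm]])) {
      ss_abort(sprintf("configuration parameter %s must be numeric of length %d",
                       nm, length(cfg[[nm]])))
    }
    cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Run the simulate/events/ratios pipeline end to end
#'
#' Simulates a genome with planted events, detects events, quantifies
#' splicing ratios across stages, builds the filtered ratio matrix, and
#' writes every product (GTF, FASTA, event TSV, FPKM TSV, ratio TSV) plus
#' a machine-readable run manifest capturing inputs, parameters, package
#' version and seed.
#'
#' @param outdir Output directory (created if needed).
#' @param config From [pipeline_config()].
#' @param n_genes Genes to simulate (default 40).
#' @param seed Seed; defaults to `config$seed`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(outdir, config = pipeline_config(), n_genes = 40,
                         seed = config$seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(n_genes = n_genes, seed = seed)
  write_gtf(sim$exons, file.path(outdir, "models.gtf"))
  Biostrings::writeXStringSet(sim$genome, file.path(outdir, "genome.fa"))
  events <- detect_events(sim$exons)
  write_events(events, file.path(outdir, "events.tsv"))
  expr <- simulate_expression(sim, seed = seed)
  write.table(expr$fpkm, file.path(outdir, "fpkm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ratios <- event_ratios(events, expr$fpkm)
  m <- build_ratio_matrix(ratios, min_fpkm = config$min_fpkm,
                          bounds = config$ratio_bounds)
  write_ratio_matrix(m, file.path(outdir, "ratio_matrix.tsv"))
  manifest <- list(
    package = "splicescape",
    version = as.character(utils::packageVersion("splicescape")),
    seed = seed,
    n_genes = n_genes,
    parameters = config,
    outputs = list(
      models = "models.gtf", genome = "genome.fa", events = "events.tsv",
      fpkm = "fpkm.tsv", ratio_matrix = "ratio_matrix.tsv"),
    counts = list(genes = dplyr::n_distinct(sim$exons$gene_id),
                  transcripts = dplyr::n_distinct(sim$exons$transcript_id),
                  events = nrow(events), retained_events = nrow(m))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
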