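#' Shannon entropy of junction alignment offsets
#'
#' Junction-spanning reads that pile up at a single alignment offset are a
#' hallmark of alignment artifacts; genuine junctions accumulate reads at
#' many distinct offsets. The score is the Shannon entropy (bits) of the
#' offset distribution.
#'
#' @param counts Non-negative read counts per offset (named or not).
#' @return Entropy in bits.
#' @export
junction_entropy <- function(counts) {
  if (any(counts < 0)) ss_abort("offset counts must be non-negative")
  total <- sum(counts)
  if (total < 1) ss_abort("junction has zero reads")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Junction entropy filter
#'
#' @param counts Offset counts for one junction.
#' @param min_entropy Threshold in bits; junctions pass with entropy
#'   strictly above it.
#' @return Logical.
#' @export
pass_junction_filter <- function(counts, min_entropy = 2) {
  junction_entropy(counts) > min_entropy
}

#' Per-junction entropy over an evidence table
#'
#' @param evidence Tibble with columns `junction_id`, `offset`, `count`.
#' @param min_entropy Passed to [pass_junction_filter()].
#' @return Tibble with `junction_id`, `total_reads`, `entropy`, `pass`.
#' @export
junction_filter <- function(evidence, min_entropy = 2) {
  assert_cols(evidence, c("junction_id", "offset", "count"))
  evidence %>%
    group_by(.data$junction_id) %>%
    summarise(total_reads = sum(.data$count),
              entropy = junction_entropy(.data$count), .groups = "drop") %>%
    mutate(pass = .data$entropy > min_entropy)
}

#' Retained-intron coverage and retention metrics
#'
#' The depth requirement ("median coverage of 10 over at least 90% of the
#' intron") is evaluated as both of its readings and both are reported:
#' the median of per-base depth must reach `min_depth`, and at least
#' `min_covered` of intron bases must individually reach `min_depth`.
#' The intron-retention percentage is `100 * b / (b + s)` where `b` counts
#' reads spanning an exon-intron boundary and `s` reads spanning the
#' spliced junction.
#'
#' @param depth Integer vector of per-base intron coverage.
#' @param boundary_reads,spliced_reads Read counts.
#' @param min_depth Depth threshold (default 10).
#' @param min_covered Required fraction of bases at `min_depth` (default 0.9).
#' @return One-row tibble: `covered_fraction` (bases with any coverage),
#'   `median_depth`, `frac_at_min_depth`, `depth_pass_median`,
#'   `depth_pass_fraction`, `depth_pass` (both), `ir_percent`.
#' @export
intron_retention_metrics <- function(depth, boundary_reads, spliced_reads,
                                     min_depth = 10, min_covered = 0.9) {
  if (length(depth) < 1) ss_abort("intron length must be >= 1")
  if (any(depth < 0) || boundary_reads < 0 || spliced_reads < 0) {
    ss_abort("negative counts")
  }
  med <- median(depth)
  frac <- mean(depth >= min_depth)
  tot <- boundary_reads + spliced_reads
  tibble(
    covered_fraction = mean(depth >= 1),
    median_depth = med,
    frac_at_min_depth = frac,
    depth_pass_median = med >= min_depth,
    depth_pass_fraction = frac >= min_covered,
    depth_pass = med >= min_depth && frac >= min_covered,
    ir_percent = if (tot == 0) 0 else 100 * boundary_reads / tot
  )
}

#' Retained-intron filter
#'
#' Passes when the coverage requirement holds (see
#' [intron_retention_metrics()]) and the retention percentage reaches
#' `min_ir_percent`.
#'
#' @inheritParams intron_retention_metrics
#' @param min_ir_percent Minimum retention percentage (default 10).
#' @return Logical.
#' @export
pass_ir_filter <- function(depth, boundary_reads, spliced_reads,
                           min_depth = 10, min_covered = 0.9,
                           min_ir_percent = 10) {
  m <- intron_retention_metrics(depth, boundary_reads, spliced_reads,
                                min_depth, min_covered)
  m$depth_pass && m$ir_percent >= min_ir_percent
}

#' Isoform expression/fraction filter
#'
#' An isoform is accepted when in at least one sample it reaches
#' `min_fpkm` and at least `min_fraction` of its gene's total FPKM.
#' Samples where the gene total is zero contribute nothing.
#'
#' @param fpkm Isoform FPKM per sample.
#' @param total_fpkm Gene-level total FPKM per sample (same length,
#'   `total_fpkm >= fpkm`).
#' @param min_fpkm Minimum FPKM (default 1).
#' @param min_fraction Minimum isoform fraction (default 0.05).
#' @return Logical.
#' @export
pass_expression_filter <- function(fpkm, total_fpkm, min_fpkm = 1,
                                   min_fraction = 0.05) {
  if (length(fpkm) != length(total_fpkm)) ss_abort("length mismatch")
  if (any(total_fpkm + 1e-9 < fpkm)) ss_abort("gene total below isoform FPKM")
  ok <- total_fpkm > 0 & fpkm >= min_fpkm & fpkm / total_fpkm >= min_fraction
  any(ok)
}
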