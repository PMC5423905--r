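#' Splicing ratio of one event in one sample
#'
#' IRR (intron retention) or PSI (exon skipping):
#' `ratio = sum(FPKM_on) / (sum(FPKM_on) + sum(FPKM_off))`, with expression
#' summed over all supporting "on" and "off" isoforms.
#'
#' @param on_fpkm,off_fpkm Summed FPKM of the on/off isoform sets.
#' @return Ratio in `[0, 1]`; `NA` when both are zero.
#' @export
event_ratio <- function(on_fpkm, off_fpkm) {
  tot <- on_fpkm + off_fpkm
  ifelse(tot > 0, on_fpkm / tot, NA_real_)
}

#' Splicing ratios for IntronR/ExonS events across samples
#'
#' @param events Event tibble (only `IntronR` and `ExonS` rows are
#'   quantified: IRR for retained introns, PSI for skipped exons).
#' @param fpkm Long tibble with columns `transcript_id`, `sample_id`,
#'   `fpkm`. Every on/off isoform of every event must be present in every
#'   sample; a missing isoform raises an error naming it.
#' @return Ratio-record tibble: `event_id`, `event_type`, `gene_id`,
#'   `sample_id`, `on_fpkm`, `off_fpkm`, `ratio`.
#' @export
event_ratios <- function(events, fpkm) {
  assert_cols(events, c("event_id", "event_type", "gene_id",
                        "on_isoforms", "off_isoforms"))
  assert_cols(fpkm, c("transcript_id", "sample_id", "fpkm"))
  ev <- events %>% filter(.data$event_type %in% c("IntronR", "ExonS"))
  long <- ev %>%
    select("event_id", "event_type", "gene_id", "on_isoforms", "off_isoforms") %>%
    tidyr::pivot_longer(c("on_isoforms", "off_isoforms"),
                        names_to = "side", values_to = "tid") %>%
    mutate(side = sub("_isoforms", "", .data$side)) %>%
    tidyr::separate_rows("tid", sep = ",")
  missing <- setdiff(unique(long$tid), unique(fpkm$transcript_id))
  if (length(missing) > 0) {
    ss_abort(sprintf("FPKM missing for isoform(s): %s",
                     paste(missing, collapse = ", ")))
  }
  long %>%
    inner_join(fpkm, by = c(tid = "transcript_id"),
               relationship = "many-to-many") %>%
    group_by(.data$event_id, .data$event_type, .data$gene_id,
             .data$sample_id, .data$side) %>%
    summarise(fpkm = sum(.data$fpkm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "side", values_from = "fpkm",
                       names_glue = "{side}_fpkm") %>%
    mutate(ratio = event_ratio(.data$on_fpkm, .data$off_fpkm))
}

#' Build a filtered events-by-samples ratio matrix
#'
#' Events are dropped when their combined on+off FPKM falls below
#' `min_fpkm` in any sample, or when any per-sample ratio falls outside
#' `bounds` (inclusive). Drop reasons are recorded in the `"dropped"`
#' attribute.
#'
#' @param ratios Ratio-record tibble from [event_ratios()].
#' @param min_fpkm Minimum on+off FPKM required in every sample (default 1).
#' @param bounds Ratio bounds applied in every sample (default
#'   `c(0.05, 0.95)`).
#' @return A wide tibble (class `ratio_matrix`): `event_id`, `event_type`,
#'   `gene_id`, then one ratio column per sample. Attributes: `dropped`
#'   (tibble of `event_id`, `reason`), `params`.
#' @export
build_ratio_matrix <- function(ratios, min_fpkm = 1, bounds = c(0.05, 0.95)) {
  flags <- ratios %>%
    group_by(.data$event_id, .data$event_type, .data$gene_id) %>%
    summarise(
      low_fpkm = any(.data$on_fpkm + .data$off_fpkm < min_fpkm),
      out_of_bounds = any(is.na(.data$ratio) | .data$ratio < bounds[1] |
                            .data$ratio > bounds[2]),
      .groups = "drop")
  dropped <- flags %>%
    filter(.data$low_fpkm | .data$out_of_bounds) %>%
    mutate(reason = dplyr::case_when(
      .data$low_fpkm & .data$out_of_bounds ~ "low_fpkm;out_of_bounds",
      .data$low_fpkm ~ "low_fpkm",
      TRUE ~ "out_of_bounds")) %>%
    select("event_id", "reason")
  wide <- ratios %>%
    anti_join(dropped, by = "event_id") %>%
    select("event_id", "event_type", "gene_id", "sample_id", "ratio") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "ratio")
  structure(wide,
            dropped = dropped,
            params = list(min_fpkm = min_fpkm, bounds = bounds),
            class = c("ratio_matrix", class(wide)))
}

ratio_values <- function(m) {
  as.matrix(m[, setdiff(names(m), c("event_id", "event_type", "gene_id")),
              drop = FALSE])
}

#' Ward clustering of a ratio matrix
#'
#' Agglomerative minimum-variance (Ward) clustering on Euclidean distances,
#' optionally after a `log(x + eps)` transform, as used for tissue/stage
#' splicing-ratio heatmaps.
#'
#' @param m A `ratio_matrix` (rows clustered) or any numeric matrix.
#' @param log_transform Apply `log(x + eps)` first (default `TRUE`).
#' @param eps Offset inside the log (default `1e-6`).
#' @return An object of class `ward_clust`: list with the `hclust` fit,
#'   `order` (leaf order), `labels`, and `height`s.
#' @export
ward_order <- function(m, log_transform = TRUE, eps = 1e-6) {
  x <- if (inherits(m, "ratio_matrix")) ratio_values(m) else as.matrix(m)
  labels <- if (inherits(m, "ratio_matrix")) m$event_id else rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  if (nrow(x) < 2) ss_abort("need at least 2 rows to cluster")
  if (log_transform) x <- log(x + eps)
  hc <- hclust(dist(x), method = "ward.D2")
  hc$labels <- labels
  structure(list(hclust = hc, order = hc$order, labels = labels,
                 height = hc$height),
            class = "ward_clust")
}

#' Export a Ward dendrogram as a Newick string
#'
#' @param w A `ward_clust` from [ward_order()].
#' @return Newick string.
#' @export
as_newick <- function(w) {
  stopifnot(inherits(w, "ward_clust"))
  ape::write.tree(ape::as.phylo(w$hclust))
}

#' Select events by ratio change between two stages
#'
#' Keeps events whose ratio increases strictly more than `threshold` from
#' `stage_a` to `stage_b` (e.g. the seed-development day-38 minus day-0
#' IRR contrast).
#'
#' @param m A `ratio_matrix`.
#' @param stage_a,stage_b Sample column names.
#' @param threshold Strict lower bound on `ratio_b - ratio_a`
#'   (default 0.15).
#' @return Tibble of selected events with `ratio_a`, `ratio_b`, `delta`.
#' @export
delta_ratio_select <- function(m, stage_a, stage_b, threshold = 0.15) {
  assert_cols(m, c("event_id", stage_a, stage_b))
  tibble(event_id = m$event_id,
         ratio_a = m[[stage_a]], ratio_b = m[[stage_b]]) %>%
    mutate(delta = .data$ratio_b - .data$ratio_a) %>%
    filter(.data$delta > threshold)
}

#' Two-sample expression shift test
#'
#' Equal-variance two-sided Student's t-test on (optionally
#' log-transformed) expression values, as used to compare gene expression
#' between developmental stages.
#'
#' @param expr_a,expr_b Replicate expression values per group.
#' @param log_transform Test `log(x + eps)` (default `TRUE`).
#' @param eps Offset inside the log.
#' @return One-row tibble: `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
expression_shift_test <- function(expr_a, expr_b, log_transform = TRUE,
                                  eps = 1e-6) {
  a <- if (log_transform) log(expr_a + eps) else expr_a
  b <- if (log_transform) log(expr_b + eps) else expr_b
  df <- length(a) + length(b) - 2
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  if (pooled_var == 0) {
    t_stat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    p <- if (t_stat == 0) 1 else 0
    return(tibble(statistic = t_stat, p_value = p, df = df,
                  mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Root Jensen-Shannon divergence between isoform-fraction vectors
#'
#' The square root of the Jensen-Shannon divergence (log base 2) between
#' two isoform-fraction distributions; a metric in `[0, 1]` used here as
#' the gene-level differential-splicing statistic.
#'
#' @param frac_a,frac_b Isoform-fraction vectors (same length >= 2, each
#'   summing to 1 within 1e-9).
#' @return Number in `[0, 1]`.
#' @export
jsd_splice_divergence <- function(frac_a, frac_b) {
  if (length(frac_a) != length(frac_b) || length(frac_a) < 2) {
    ss_abort("fraction vectors must have equal length >= 2")
  }
  if (abs(sum(frac_a) - 1) > 1e-9 || abs(sum(frac_b) - 1) > 1e-9) {
    ss_abort("fraction vectors must sum to 1")
  }
  m <- (frac_a + frac_b) / 2
  kl <- function(p, q) {
    i <- p > 0
    sum(p[i] * log2(p[i] / q[i]))
  }
  sqrt(pmax(0, (kl(frac_a, m) + kl(frac_b, m)) / 2))
}

#' Permutation test for differential splicing via root-JSD
#'
#' Computes the root Jensen-Shannon divergence between the mean
#' isoform-fraction vectors of two replicate groups and a permutation
#' p-value by shuffling replicate labels.
#'
#' @param fpkm_a,fpkm_b Matrices (isoforms x replicates) of isoform FPKM
#'   per condition.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Seed for the permutation draw.
#' @return One-row tibble: `jsd`, `p_value`, `n_perm`.
#' @export
jsd_permutation_test <- function(fpkm_a, fpkm_b, n_perm = 1000, seed = 1) {
  fpkm_a <- as.matrix(fpkm_a); fpkm_b <- as.matrix(fpkm_b)
  if (nrow(fpkm_a) != nrow(fpkm_b)) ss_abort("isoform count mismatch")
  fracs <- function(m) {
    cs <- colSums(m)
    if (any(cs == 0)) ss_abort("replicate with zero total FPKM")
    rowMeans(sweep(m, 2, cs, "/"))
  }
  stat <- function(ma, mb) jsd_splice_divergence(fracs(ma), fracs(mb))
  obs <- stat(fpkm_a, fpkm_b)
  all_m <- cbind(fpkm_a, fpkm_b)
  na <- ncol(fpkm_a)
  perm <- withr::with_seed(seed, {
    replicate(n_perm, {
      idx <- sample(ncol(all_m))
      stat(all_m[, idx[seq_len(na)], drop = FALSE],
           all_m[, idx[-seq_len(na)], drop = FALSE])
    })
  })
  tibble(jsd = obs, p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
         n_perm = n_perm)
}

#' Post-filter differential-splicing gene calls
#'
#' Keeps genes where at least one isoform reaches `min_fpkm` in each
#' condition, and at least one isoform is more abundant in each condition
#' (so the change is a redistribution, not a one-sided shift).
#'
#' @param tbl Tibble with columns `gene_id`, `transcript_id`, `fpkm_a`,
#'   `fpkm_b`.
#' @param min_fpkm Per-condition expression floor (default 5).
#' @return Gene-level tibble of retained genes with the filter columns.
#' @export
diff_splice_postfilter <- function(tbl, min_fpkm = 5) {
  assert_cols(tbl, c("gene_id", "transcript_id", "fpkm_a", "fpkm_b"))
  tbl %>%
    group_by(.data$gene_id) %>%
    summarise(
      max_a = max(.data$fpkm_a), max_b = max(.data$fpkm_b),
      higher_in_a = any(.data$fpkm_a > .data$fpkm_b),
      higher_in_b = any(.data$fpkm_b > .data$fpkm_a),
      .groups = "drop") %>%
    filter(.data$max_a >= min_fpkm, .data$max_b >= min_fpkm,
           .data$higher_in_a, .data$higher_in_b)
}

#' Presence-absence variation calls for isoforms
#'
#' An isoform is PAV when its expression is strictly above `high` in one
#' sample and strictly below `low` in the other.
#'
#' @param tbl Tibble with `transcript_id`, `fpkm_a`, `fpkm_b`.
#' @param high Upper threshold (default 2).
#' @param low Lower threshold (default 0.1).
#' @return `tbl` with a `pav` column: `"PAV-in-A"`, `"PAV-in-B"`, `"none"`.
#' @export
pav_isoforms <- function(tbl, high = 2, low = 0.1) {
  assert_cols(tbl, c("transcript_id", "fpkm_a", "fpkm_b"))
  tbl %>%
    mutate(pav = dplyr::case_when(
      .data$fpkm_a > high & .data$fpkm_b < low ~ "PAV-in-A",
      .data$fpkm_b > high & .data$fpkm_a < low ~ "PAV-in-B",
      TRUE ~ "none"))
}

#' Write a ratio matrix as TSV
#'
#' @param m A `ratio_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratio_matrix <- function(m, path) {
  write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
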