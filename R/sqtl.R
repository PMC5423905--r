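#' Splicing frequency of a junction
#'
#' The proportion of junction-spanning reads among all reads of the
#' containing gene: `y / (y + r)` where `r` counts same-gene reads not on
#' the junction.
#'
#' @param y Junction-spanning read counts.
#' @param r Other same-gene read counts.
#' @return Proportion; `NA` where `y + r == 0` (such lines are excluded
#'   from model fits).
#' @export
splicing_frequency <- function(y, r) {
  tot <- y + r
  ifelse(tot > 0, y / tot, NA_real_)
}

#' Junction eligibility filter for sQTL mapping
#'
#' A junction enters the scan when its total spanning reads reach
#' `min_spanning` and its mean spanning reads per line reach
#' `min_mean_per_line`.
#'
#' @param counts Long tibble with columns `junction_id`, `line_id`, `y`
#'   (junction reads), `r` (other gene reads).
#' @param min_spanning Total spanning-read floor (default 20).
#' @param min_mean_per_line Mean per-line floor (default 5).
#' @return Tibble of eligible junctions with `total_y` and `mean_y`.
#' @export
eligible_junctions <- function(counts, min_spanning = 20,
                               min_mean_per_line = 5) {
  assert_cols(counts, c("junction_id", "line_id", "y"))
  counts %>%
    group_by(.data$junction_id) %>%
    summarise(total_y = sum(.data$y), mean_y = mean(.data$y),
              .groups = "drop") %>%
    filter(.data$total_y >= min_spanning, .data$mean_y >= min_mean_per_line)
}

#' Quasi-binomial GLM for splicing frequencies
#'
#' Logit-link binomial regression of junction-spanning counts on a design,
#' with overdispersion control: the dispersion is estimated as Pearson
#' chi-square / residual df, and coefficient tests are t-tests on the
#' dispersion-scaled standard errors (R's `glm` with the `quasibinomial`
#' family). Complete separation is detected and handled by refitting with
#' Haldane-style pseudo-counts (`y + 0.25`, `n + 0.5`) and flagging the
#' fit.
#'
#' @param y Junction-spanning read counts per observation.
#' @param n Total gene reads per observation (`n >= y`).
#' @param design Model data: a data frame of covariates (a formula over
#'   its columns is built as `~ .`), or a one-column data frame/vector for
#'   the single-genotype model.
#' @return An object of class `sqtl_fit`: list with `coefficients`
#'   (tibble: term, estimate, std_error, statistic, p_value), `dispersion`,
#'   `df_residual`, `separated`, `converged`, and the underlying `glm`.
#' @export
quasibinomial_fit <- function(y, n, design) {
  if (any(n < y)) ss_abort("n must be >= y")
  dat <- as.data.frame(design)
  keep <- n > 0 & stats::complete.cases(dat)
  y <- y[keep]; n <- n[keep]; dat <- dat[keep, , drop = FALSE]
  if (length(y) < ncol(dat) + 2) ss_abort("too few informative observations")
  fit_once <- function(yy, nn) {
    glm(cbind(yy, nn - yy) ~ ., family = quasibinomial(), data = dat,
        control = list(maxit = 100))
  }
  fit <- fit_once(y, n)
  mu <- fit$fitted.values
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8)
  if (separated) {
    fit <- fit_once(y + 0.25, n + 0.5)
  }
  if (!fit$converged) ss_abort("quasi-binomial IRLS did not converge")
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    coefficients = tibble(
      term = rownames(co), estimate = co[, 1], std_error = co[, 2],
      statistic = co[, 3], p_value = co[, 4]),
    dispersion = sm$dispersion,
    df_residual = fit$df.residual,
    separated = separated,
    converged = fit$converged,
    fit = fit
  ), class = "sqtl_fit")
}

#' @export
print.sqtl_fit <- function(x, ...) {
  cat("Quasi-binomial splicing-frequency fit\n")
  cat(sprintf("  dispersion phi = %.3f on %d df%s\n", x$dispersion,
              x$df_residual, if (x$separated) " (separated; penalized)" else ""))
  print(x$coefficients)
  invisible(x)
}

#' @rdname quasibinomial_fit
#' @param x An `sqtl_fit`.
#' @param ... Unused.
#' @export
tidy.sqtl_fit <- function(x, ...) x$coefficients

#' @rdname quasibinomial_fit
#' @export
glance.sqtl_fit <- function(x, ...) {
  tibble(dispersion = x$dispersion, df_residual = x$df_residual,
         separated = x$separated, converged = x$converged)
}

# genotype of the segment containing each junction (cis marker), NA when
# no segment contains the position
cis_marker_of <- function(junction_meta, markers) {
  purrr::map_chr(seq_len(nrow(junction_meta)), function(i) {
    hit <- markers$chrom == junction_meta$chrom[i] &
      markers$start <= junction_meta$pos[i] &
      junction_meta$pos[i] < markers$end
    if (!any(hit)) NA_character_ else markers$marker_id[which(hit)[1]]
  })
}

genotype_vector <- function(genotypes, marker_id, line_ids) {
  g <- genotypes %>% filter(.data$marker_id == !!marker_id)
  g <- setNames(g$genotype, g$line_id)[line_ids]
  ifelse(g == "M", 1, ifelse(g == "B", 0, NA))
}

#' Genome-wide cis splicing-QTL scan
#'
#' For each junction, fits `logit(p) = b0 + b1 * G` where `G` is the
#' genotype (B = 0, Mo17-type M = 1) of the marker segment containing the
#' junction, using [quasibinomial_fit()]. Benjamini-Hochberg FDR is
#' applied across junctions; significant junctions are additionally
#' annotated with whether they pass a fold-change filter on the splicing
#' odds.
#'
#' @param panel List with `markers` (tibble: `marker_id`, `chrom`, `start`,
#'   `end`) and `genotypes` (tibble: `line_id`, `marker_id`, `genotype` in
#'   B/M, possibly `NA`).
#' @param counts Long junction count tibble (`junction_id`, `line_id`,
#'   `y`, `r`).
#' @param junction_meta Tibble: `junction_id`, `chrom`, `pos`.
#' @param fdr FDR level (default 0.05).
#' @param fold Odds fold-change threshold (default 2).
#' @return A tibble of class `sqtl_scan`: one row per junction with
#'   `marker_id`, `beta`, `dispersion`, `p_value`, `q_value`,
#'   `significant`, `odds_fold_change`, `fold_pass`, `direction`
#'   (`up_in_M`/`up_in_B`), `separated`.
#' @export
cis_scan <- function(panel, counts, junction_meta, fdr = 0.05, fold = 2) {
  assert_cols(junction_meta, c("junction_id", "chrom", "pos"))
  junction_meta <- junction_meta %>%
    mutate(marker_id = cis_marker_of(junction_meta, panel$markers)) %>%
    filter(!is.na(.data$marker_id))
  res <- purrr::map(seq_len(nrow(junction_meta)), function(i) {
    jm <- junction_meta[i, ]
    cc <- counts %>% filter(.data$junction_id == jm$junction_id)
    G <- genotype_vector(panel$genotypes, jm$marker_id, cc$line_id)
    f <- quasibinomial_fit(cc$y, cc$y + cc$r, data.frame(G = G))
    b <- f$coefficients[f$coefficients$term == "G", ]
    tibble(junction_id = jm$junction_id, marker_id = jm$marker_id,
           scope = "cis", beta = b$estimate, dispersion = f$dispersion,
           p_value = b$p_value, separated = f$separated)
  })
  out <- bind_rows(res) %>%
    mutate(q_value = p.adjust(.data$p_value, method = "BH"),
           significant = .data$q_value <= fdr,
           odds_fold_change = exp(abs(.data$beta)),
           fold_pass = .data$odds_fold_change >= fold,
           direction = if_else(.data$beta > 0, "up_in_M", "up_in_B"))
  structure(out, class = c("sqtl_scan", class(out)))
}

#' Trans splicing-QTL scan for one junction
#'
#' Tests every marker on chromosomes other than the junction's own against
#' the junction's splicing frequency with the interaction model
#' `logit(p) = b0 + b1 G_cis + b2 G_trans + b3 G_cis:G_trans`, reporting
#' the trans main effect and the interaction.
#'
#' @inheritParams cis_scan
#' @param junction_id Junction to scan.
#' @return Tibble: one row per trans marker with `beta_trans`,
#'   `beta_interaction`, `p_trans`, `p_interaction`, `dispersion`.
#' @export
trans_scan <- function(panel, counts, junction_meta, junction_id) {
  jm <- junction_meta %>% filter(.data$junction_id == !!junction_id)
  if (nrow(jm) != 1) ss_abort("unknown junction_id")
  cis_id <- cis_marker_of(jm, panel$markers)
  cc <- counts %>% filter(.data$junction_id == !!junction_id)
  g_cis <- genotype_vector(panel$genotypes, cis_id, cc$line_id)
  trans_markers <- panel$markers %>% filter(.data$chrom != jm$chrom)
  if (nrow(trans_markers) == 0) ss_abort("no trans markers available")
  res <- purrr::map(trans_markers$marker_id, function(mid) {
    g_tr <- genotype_vector(panel$genotypes, mid, cc$line_id)
    f <- quasibinomial_fit(
      cc$y, cc$y + cc$r,
      data.frame(G_cis = g_cis, G_trans = g_tr,
                 G_inter = g_cis * g_tr))
    co <- f$coefficients
    tibble(junction_id = junction_id, marker_id = mid, scope = "trans",
           beta_trans = co$estimate[co$term == "G_trans"],
           beta_interaction = co$estimate[co$term == "G_inter"],
           p_trans = co$p_value[co$term == "G_trans"],
           p_interaction = co$p_value[co$term == "G_inter"],
           dispersion = f$dispersion, separated = f$separated)
  })
  bind_rows(res)
}

#' Modified Bonferroni cutoff for the trans scan
#'
#' Chromosomes are divided into `regions_per_chrom` equal-bp regions;
#' markers within a region count as a single effective marker. The total
#' test count is, summed over junctions, the number of occupied regions on
#' chromosomes other than the junction's own; the cutoff is
#' `alpha / total`.
#'
#' @param markers Marker tibble (`marker_id`, `chrom`, `start`, `end`).
#' @param junction_meta Junction tibble (`junction_id`, `chrom`).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param regions_per_chrom Regions per chromosome (default 100).
#' @param alpha Family-wise level (default 0.05).
#' @return The p-value cutoff (scalar).
#' @export
trans_cutoff <- function(markers, junction_meta, chrom_lengths,
                         regions_per_chrom = 100, alpha = 0.05) {
  occupied <- markers %>%
    mutate(mid = (.data$start + .data$end) / 2,
           len = unname(chrom_lengths[.data$chrom]),
           region = pmin(floor(regions_per_chrom * .data$mid / .data$len),
                         regions_per_chrom - 1)) %>%
    distinct(.data$chrom, .data$region) %>%
    dplyr::count(.data$chrom, name = "n_regions")
  per_junction <- purrr::map_dbl(junction_meta$chrom, function(ch) {
    sum(occupied$n_regions[occupied$chrom != ch])
  })
  total <- sum(per_junction)
  if (total == 0) ss_abort("no trans markers: zero effective tests")
  alpha / total
}

#' Splice-site SNP windows
#'
#' The strand-aware 12-bp scoring windows around each junction: a 9-bp
#' donor window (last 3 exonic + first 6 intronic bases, consensus
#' CAG|GURAGU) and a 3-bp acceptor window (last 2 intronic + first exonic
#' base, consensus AG|G).
#'
#' @param junctions Junction tibble with `chrom`, `intron_start`,
#'   `intron_end`, `strand`.
#' @return `junctions` with `donor_win_start`, `donor_win_end`,
#'   `acceptor_win_start`, `acceptor_win_end` (0-based half-open).
#' @export
splice_site_windows <- function(junctions) {
  assert_cols(junctions, c("chrom", "intron_start", "intron_end", "strand"))
  junctions %>%
    mutate(
      donor_win_start = if_else(.data$strand == "+",
                                .data$intron_start - 3L, .data$intron_end - 6L),
      donor_win_end = if_else(.data$strand == "+",
                              .data$intron_start + 6L, .data$intron_end + 3L),
      acceptor_win_start = if_else(.data$strand == "+",
                                   .data$intron_end - 2L, .data$intron_start - 1L),
      acceptor_win_end = if_else(.data$strand == "+",
                                 .data$intron_end + 1L, .data$intron_start + 2L))
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' Closed form `N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))` with the
#' continuity correction clamped at zero, and the upper-tail p-value on
#' 1 df.
#'
#' @param tab 2x2 matrix of counts.
#' @return One-row tibble: `chisq`, `p_value`.
#' @export
yates_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) ss_abort("need a 2x2 table")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  num <- n * max(0, abs(a * d - b * c) - n / 2)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chisq <- if (den == 0) 0 else num / den
  tibble(chisq = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' SNP enrichment in splice-site windows of significant junctions
#'
#' Counts junctions with at least one SNP inside their 12-bp splice-site
#' windows among significant cis-sQTL junctions versus all remaining
#' junctions, and tests enrichment with the Yates-corrected chi-square.
#'
#' @param sig_junctions,all_junctions Junction tibbles (`junction_id`,
#'   `chrom`, `intron_start`, `intron_end`, `strand`); `sig_junctions`
#'   must be a subset of `all_junctions`.
#' @param snps Tibble of SNP positions: `chrom`, `pos` (0-based).
#' @return List with `table` (2x2 counts), `chisq`, `p_value`.
#' @export
snp_enrichment <- function(sig_junctions, all_junctions, snps) {
  w <- splice_site_windows(all_junctions)
  win <- GenomicRanges::GRanges(
    rep(w$chrom, 2),
    IRanges::IRanges(start = c(w$donor_win_start, w$acceptor_win_start) + 1L,
                     end = c(w$donor_win_end, w$acceptor_win_end)))
  sp <- GenomicRanges::GRanges(snps$chrom,
                               IRanges::IRanges(start = snps$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(win, sp)
  has_snp_idx <- unique((S4Vectors::queryHits(hits) - 1L) %% nrow(w) + 1L)
  has_snp <- w$junction_id %in% w$junction_id[has_snp_idx]
  is_sig <- w$junction_id %in% sig_junctions$junction_id
  tab <- matrix(c(sum(is_sig & has_snp), sum(is_sig & !has_snp),
                  sum(!is_sig & has_snp), sum(!is_sig & !has_snp)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("sig", "other"), c("snp", "no_snp")))
  yc <- yates_chisq(tab)
  list(table = tab, chisq = yc$chisq, p_value = yc$p_value)
}

#' Fraction of sQTLs near splicing-related genes
#'
#' For each sQTL position, checks whether any gene interval lies within
#' `window_bp` on either side.
#'
#' @param sqtl_positions Tibble: `chrom`, `pos`.
#' @param genes Tibble of gene intervals: `chrom`, `start`, `end`.
#' @param window_bp Flanking window in bp (e.g. `1e6`, `1e7`).
#' @return Fraction in `[0, 1]` of sQTLs with at least one gene in range.
#' @export
proximity_overlap <- function(sqtl_positions, genes, window_bp) {
  if (nrow(sqtl_positions) == 0) return(NA_real_)
  q <- GenomicRanges::GRanges(
    sqtl_positions$chrom,
    IRanges::IRanges(start = pmax(1L, sqtl_positions$pos + 1L - window_bp),
                     end = sqtl_positions$pos + window_bp))
  s <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(start = genes$start + 1L,
                                               end = genes$end))
  hits <- GenomicRanges::countOverlaps(q, s)
  mean(hits > 0)
}
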