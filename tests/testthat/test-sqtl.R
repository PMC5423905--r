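test_that("splicing frequency and junction eligibility follow the count rules", {
  expect_equal(splicing_frequency(20, 80), 0.2)
  expect_equal(splicing_frequency(0, 50), 0)
  expect_equal(splicing_frequency(50, 0), 1)
  expect_true(is.na(splicing_frequency(0, 0)))

  counts <- tibble::tibble(
    junction_id = rep(c("j_few", "j_edge", "j_rich"), each = 105),
    line_id = rep(sprintf("L%03d", 1:105), 3),
    y = c(rep(c(1, 0), length.out = 105) * 0 + c(rep(1, 19), rep(0, 86)),
          rep(5, 105),
          rpois(105, 30) + 10),
    r = 50)
  el <- eligible_junctions(counts)
  expect_false("j_few" %in% el$junction_id)   # 19 total reads
  expect_true("j_edge" %in% el$junction_id)   # mean exactly 5.0
  expect_true("j_rich" %in% el$junction_id)

  set.seed(21)
  rnd <- tibble::tibble(
    junction_id = rep(sprintf("j%02d", 1:30), each = 10),
    line_id = rep(sprintf("L%02d", 1:10), 30),
    y = rpois(300, 6), r = rpois(300, 40))
  got <- sort(eligible_junctions(rnd)$junction_id)
  want <- character(0)
  for (j in unique(rnd$junction_id)) {
    yy <- rnd$y[rnd$junction_id == j]
    if (sum(yy) >= 20 && mean(yy) >= 5) want <- c(want, j)
  }
  expect_equal(got, sort(want))
})

test_that("quasi-binomial fit is calibrated and recovers null structure", {
  set.seed(31)
  # identical pooled proportions in both groups -> beta exactly 0, p = 1
  G <- rep(0:1, each = 4)
  n <- rep(50L, 8)
  y <- c(10L, 30L, 20L, 20L, 15L, 25L, 18L, 22L)
  f <- quasibinomial_fit(y, n, data.frame(G = G))
  b <- f$coefficients[f$coefficients$term == "G", ]
  expect_lt(abs(b$estimate), 1e-8)
  expect_gt(b$p_value, 0.99)

  # pure binomial data: dispersion near 1
  phis <- replicate(40, {
    G <- rep(0:1, each = 50)
    n <- rpois(100, 60) + 1
    y <- rbinom(100, n, 0.25)
    quasibinomial_fit(y, n, data.frame(G = G))$dispersion
  })
  expect_gt(median(phis), 0.7)
  expect_lt(median(phis), 1.3)

  # tidy/glance accessors
  expect_s3_class(tidy(f), "tbl_df")
  expect_named(glance(f),
               c("dispersion", "df_residual", "separated", "converged"))
})

test_that("swapping genotype labels negates the effect exactly", {
  set.seed(52)
  G <- rep(0:1, each = 40)
  n <- rpois(80, 50) + 1
  y <- rbinom(80, n, stats::plogis(-1 + 0.8 * G))
  f1 <- quasibinomial_fit(y, n, data.frame(G = G))
  f2 <- quasibinomial_fit(y, n, data.frame(G = 1 - G))
  b1 <- f1$coefficients$estimate[f1$coefficients$term == "G"]
  b2 <- f2$coefficients$estimate[f2$coefficients$term == "G"]
  expect_equal(b1, -b2, tolerance = 1e-8)
})

test_that("separation is flagged and handled by the penalized refit", {
  G <- rep(0:1, each = 10)
  y <- c(rep(0L, 10), rep(50L, 10))
  n <- rep(50L, 20)
  f <- suppressWarnings(quasibinomial_fit(y, n, data.frame(G = G)))
  expect_true(f$separated)
  expect_true(all(is.finite(f$coefficients$estimate)))
})

test_that("cis scan detects a planted effect and BH matches hand computation", {
  # step-up: q3 = 0.02*4/3, q2 = min(q3, 0.01*4/2) = 0.02, q1 = 0.004
  expect_equal(p.adjust(c(0.001, 0.01, 0.02, 0.9), method = "BH"),
               c(0.004, 0.02, 0.02 * 4 / 3, 0.9))
  eff <- tibble::tibble(junction_id = "jx001", beta_cis = log(2.5),
                        beta_trans = NA_real_, beta_inter = NA_real_,
                        trans_marker = NA_character_)
  rp <- simulate_ril_panel(n_lines = 100, n_junctions = 8, effects = eff,
                           seed = 61)
  sc <- cis_scan(rp$panel, rp$counts, rp$junction_meta)
  hit <- sc[sc$junction_id == "jx001", ]
  expect_true(hit$significant)
  expect_true(hit$fold_pass)
  expect_equal(hit$direction, "up_in_M")
  expect_lt(abs(hit$beta - log(2.5)), 0.5)
  # q-values are monotone in p
  ord <- order(sc$p_value)
  expect_true(all(diff(sc$q_value[ord]) >= -1e-12))
})

test_that("trans scan separates main trans effects from interactions", {
  # junction positions do not depend on the planted effects, so a probe
  # run identifies which chromosome is trans for jx001
  probe <- simulate_ril_panel(n_lines = 120, n_junctions = 2, depth = 60,
                              seed = 71)
  cis_chrom <- probe$junction_meta$chrom[
    probe$junction_meta$junction_id == "jx001"]
  trans_marker <- sprintf("%s_m05", setdiff(c("chr1", "chr2"), cis_chrom))

  eff_main <- tibble::tibble(junction_id = "jx001", beta_cis = 0,
                             beta_trans = 1.0, beta_inter = 0,
                             trans_marker = trans_marker)
  rp <- simulate_ril_panel(n_lines = 120, n_junctions = 2,
                           effects = eff_main, depth = 60, seed = 71)
  ts <- trans_scan(rp$panel, rp$counts, rp$junction_meta, "jx001")
  row <- ts[ts$marker_id == trans_marker, ]
  expect_lt(row$p_trans, 1e-4)
  expect_gt(row$p_interaction, 0.01)

  probe2 <- simulate_ril_panel(n_lines = 120, n_junctions = 2, depth = 60,
                               seed = 72)
  cis2 <- probe2$junction_meta$chrom[
    probe2$junction_meta$junction_id == "jx001"]
  tm2 <- sprintf("%s_m05", setdiff(c("chr1", "chr2"), cis2))
  eff_int <- tibble::tibble(junction_id = "jx001", beta_cis = 0,
                            beta_trans = 0, beta_inter = 1.4,
                            trans_marker = tm2)
  rp2 <- simulate_ril_panel(n_lines = 120, n_junctions = 2,
                            effects = eff_int, depth = 60, seed = 72)
  ts2 <- trans_scan(rp2$panel, rp2$counts, rp2$junction_meta, "jx001")
  row2 <- ts2[ts2$marker_id == tm2, ]
  expect_lt(row2$p_interaction, 1e-3)
})

test_that("trans cutoff counts occupied regions on other chromosomes", {
  # 2 chromosomes, all 100 regions occupied, 10 junctions per chromosome
  markers <- tibble::tibble(
    marker_id = sprintf("m%03d", 1:200),
    chrom = rep(c("chr1", "chr2"), each = 100),
    start = rep(seq(0, 99) * 1000, 2),
    end = rep(seq(1, 100) * 1000, 2))
  jm <- tibble::tibble(junction_id = sprintf("j%02d", 1:20),
                       chrom = rep(c("chr1", "chr2"), each = 10))
  cl <- c(chr1 = 1e5, chr2 = 1e5)
  expect_equal(trans_cutoff(markers, jm, cl), 0.05 / 2000)

  # one junction; other chromosome has 37 occupied regions
  m2 <- tibble::tibble(marker_id = sprintf("m%03d", 1:37), chrom = "chr2",
                       start = seq(0, 36) * 1000, end = seq(1, 37) * 1000)
  j2 <- tibble::tibble(junction_id = "j1", chrom = "chr1")
  expect_equal(trans_cutoff(m2, j2, c(chr1 = 1e5, chr2 = 1e5)), 0.05 / 37)

  expect_error(trans_cutoff(m2, tibble::tibble(junction_id = "j1",
                                               chrom = "chr2"),
                            c(chr1 = 1e5, chr2 = 1e5)),
               "zero effective tests")
})

test_that("splice-site windows total 12 bp and mirror across strands", {
  jp <- tibble::tibble(junction_id = "j1", chrom = "chr1",
                       intron_start = 100L, intron_end = 200L, strand = "+")
  w <- splice_site_windows(jp)
  expect_equal(c(w$donor_win_start, w$donor_win_end), c(97L, 106L))
  expect_equal(c(w$acceptor_win_start, w$acceptor_win_end), c(198L, 201L))

  jm <- dplyr::mutate(jp, strand = "-")
  wm <- splice_site_windows(jm)
  expect_equal(c(wm$donor_win_start, wm$donor_win_end), c(194L, 203L))
  expect_equal(c(wm$acceptor_win_start, wm$acceptor_win_end), c(99L, 102L))

  set.seed(44)
  many <- tibble::tibble(
    junction_id = sprintf("j%d", 1:50), chrom = "chr1",
    intron_start = sample(1000:5000, 50),
    strand = sample(c("+", "-"), 50, replace = TRUE)) %>%
    dplyr::mutate(intron_end = intron_start + sample(60:3000, 50))
  ww <- splice_site_windows(many)
  expect_true(all((ww$donor_win_end - ww$donor_win_start) +
                    (ww$acceptor_win_end - ww$acceptor_win_start) == 12))
})

test_that("Yates chi-square matches the worked value and chisq.test", {
  yc <- yates_chisq(matrix(c(10, 90, 30, 70), nrow = 2, byrow = TRUE))
  expect_equal(yc$chisq, 11.28, tolerance = 0.001)
  ref <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 90, 30, 70), 2, byrow = TRUE),
                      correct = TRUE))
  expect_equal(yc$chisq, unname(ref$statistic))
  expect_equal(yc$p_value, ref$p.value)
  # identical proportions -> ~0
  expect_lt(yates_chisq(matrix(c(20, 80, 20, 80), 2, byrow = TRUE))$chisq,
            1e-12)
})

test_that("planted splice-window SNP enrichment is detected", {
  eff <- tibble::tibble(junction_id = sprintf("jx%03d", 1:10),
                        beta_cis = log(3), beta_trans = NA_real_,
                        beta_inter = NA_real_, trans_marker = NA_character_)
  rp <- simulate_ril_panel(n_lines = 60, n_junctions = 40, effects = eff,
                           snp_rate_sig = 0.9, snp_rate_null = 0.02,
                           seed = 83)
  sig <- rp$junctions %>% dplyr::filter(junction_id %in% eff$junction_id)
  enr <- snp_enrichment(sig, rp$junctions, rp$snps)
  expect_lt(enr$p_value, 0.05)
  expect_gt(enr$table["sig", "snp"] / sum(enr$table["sig", ]),
            enr$table["other", "snp"] / sum(enr$table["other", ]))
})

test_that("proximity overlap matches an all-pairs distance check", {
  sq <- tibble::tibble(chrom = "chr1", pos = c(5e6, 20e6))
  genes <- tibble::tibble(chrom = "chr1", start = 5.4e6, end = 5.6e6)
  expect_equal(proximity_overlap(sq, genes, 1e6), 0.5)
  expect_equal(proximity_overlap(sq, genes, 2e7), 1)
  g2 <- tibble::tibble(chrom = "chr1", start = 6.6e6, end = 6.7e6)
  expect_equal(proximity_overlap(sq[1, ], g2, 1e6), 0)   # 1.6 Mb away
  expect_equal(proximity_overlap(sq[1, ], g2, 1e7), 1)

  set.seed(55)
  sq <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
                       pos = sample(1e6:9e7, 60))
  genes <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                          start = sample(1e6:9e7, 30)) %>%
    dplyr::mutate(end = start + 5000)
  w <- 2e6
  brute <- mean(vapply(seq_len(nrow(sq)), function(i) {
    any(genes$chrom == sq$chrom[i] &
          genes$start < sq$pos[i] + w & genes$end > sq$pos[i] - w)
  }, logical(1)))
  expect_equal(proximity_overlap(sq, genes, w), brute)
})
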