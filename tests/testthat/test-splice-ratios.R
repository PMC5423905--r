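test_that("event_ratio implements the on/(on+off) summation rule", {
  expect_equal(event_ratio(2, 6), 0.25)
  expect_equal(event_ratio(3, 0), 1)
  expect_true(is.na(event_ratio(0, 0)))
  # summation over supporting isoforms: on {1, 2}, off {3} -> 0.5
  ev <- tibble::tibble(event_id = "e1", event_type = "IntronR",
                       gene_id = "g1", on_isoforms = "t1,t2",
                       off_isoforms = "t3")
  fpkm <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                         sample_id = "s1", fpkm = c(1, 2, 3))
  rr <- event_ratios(ev, fpkm)
  expect_equal(rr$ratio, 0.5)
  expect_equal(rr$on_fpkm, 3)
  # missing isoform is named in the error
  expect_error(event_ratios(ev, fpkm[-2, ]), "t2")
})

test_that("ratio records complement to 1 when orientation flips", {
  set.seed(4)
  on <- runif(50, 0, 10); off <- runif(50, 0, 10)
  expect_equal(event_ratio(on, off) + event_ratio(off, on), rep(1, 50))
})

test_that("ratio matrix drops out-of-bounds and low-FPKM events with reasons", {
  rr <- tibble::tibble(
    event_id = rep(c("e1", "e2", "e3", "e4"), each = 2),
    event_type = "IntronR", gene_id = "g1",
    sample_id = rep(c("s1", "s2"), 4),
    on_fpkm = c(2, 2, 9.6, 5, 0.2, 2, 4, 4),
    off_fpkm = c(2, 2, 0.4, 5, 0.2, 2, 6, 6)) %>%
    dplyr::mutate(ratio = event_ratio(on_fpkm, off_fpkm))
  m <- build_ratio_matrix(rr)
  expect_equal(m$event_id, c("e1", "e4"))
  dropped <- attr(m, "dropped")
  expect_equal(dropped$reason[dropped$event_id == "e2"], "out_of_bounds")
  expect_equal(dropped$reason[dropped$event_id == "e3"], "low_fpkm")
})

test_that("two rows merge at their Euclidean Ward distance", {
  x <- rbind(c(0, 0, 0), c(3, 4, 0))
  w <- ward_order(x, log_transform = FALSE)
  expect_equal(w$height, 5)
})

test_that("Ward merge heights match the Lance-Williams recursion", {
  set.seed(41)
  x <- matrix(runif(24), nrow = 6)
  w <- ward_order(x, log_transform = FALSE)
  expect_equal(sort(w$height), sort(oracle_ward_heights(x)),
               tolerance = 1e-10)
  # and with the log transform applied
  m <- matrix(runif(20, 0.05, 0.95), nrow = 5)
  w2 <- ward_order(m, log_transform = TRUE)
  expect_equal(sort(w2$height), sort(oracle_ward_heights(log(m + 1e-6))),
               tolerance = 1e-10)
})

test_that("the top Ward split separates planted ratio clusters", {
  set.seed(12)
  lo <- matrix(runif(40, 0.15, 0.25), nrow = 10)
  hi <- matrix(runif(40, 0.75, 0.85), nrow = 10)
  w <- ward_order(rbind(lo, hi))
  top <- stats::cutree(w$hclust, k = 2)
  expect_equal(length(unique(top[1:10])), 1)
  expect_equal(length(unique(top[11:20])), 1)
  expect_true(top[1] != top[11])
  # Newick export covers every leaf
  nw <- as_newick(w)
  expect_true(all(vapply(seq_len(20), function(i) grepl(
    paste0("(\\(|,)", i, ":"), nw), logical(1))))
})

test_that("delta selection is strict at the threshold", {
  m <- structure(
    tibble::tibble(event_id = c("e1", "e2", "e3"),
                   event_type = "IntronR", gene_id = "g1",
                   d0 = c(0.2, 0.2, 0.2), d38 = c(0.36, 0.35, 0.5)),
    class = c("ratio_matrix", "tbl_df", "tbl", "data.frame"))
  sel <- delta_ratio_select(m, "d0", "d38")
  expect_setequal(sel$event_id, c("e1", "e3"))
  expect_equal(sel$delta[sel$event_id == "e1"], 0.16)
})

test_that("expression shift test matches the textbook pooled-variance formula", {
  t0 <- expression_shift_test(c(1, 2, 3), c(1, 2, 3), log_transform = FALSE)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # identical constant groups: degenerate but well-defined
  tc <- expression_shift_test(c(2, 2, 2), c(2, 2, 2), log_transform = FALSE)
  expect_equal(c(tc$statistic, tc$p_value), c(0, 1))

  a <- c(1.1, 2.3, 3.1); b <- c(4.0, 5.2, 6.5)
  got <- expression_shift_test(a, b, log_transform = FALSE)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$statistic, t_hand)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), df = 4))
})

test_that("root-JSD has the closed-form values and metric behavior", {
  expect_equal(jsd_splice_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(jsd_splice_divergence(c(1, 0), c(0, 1)), 1)
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  m <- (p + q) / 2
  hand <- sqrt(0.5 * sum(p * log2(p / m)) + 0.5 * sum(q * log2(q / m)))
  expect_equal(jsd_splice_divergence(p, q), hand)
  # symmetry and triangle inequality on random triples
  set.seed(33)
  for (k in 1:20) {
    u <- stats::rgamma(3, 1); u <- u / sum(u)
    v <- stats::rgamma(3, 1); v <- v / sum(v)
    z <- stats::rgamma(3, 1); z <- z / sum(z)
    expect_equal(jsd_splice_divergence(u, v), jsd_splice_divergence(v, u))
    expect_lte(jsd_splice_divergence(u, v),
               jsd_splice_divergence(u, z) + jsd_splice_divergence(z, v) + 1e-12)
  }
  expect_error(jsd_splice_divergence(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
})

test_that("root-JSD permutation test flags redistributed isoform fractions", {
  set.seed(6)
  base_a <- c(0.8, 0.2); base_b <- c(0.2, 0.8)
  mk <- function(frac) {
    sapply(1:6, function(i) frac * exp(rnorm(2, 0, 0.05)) * 50)
  }
  shifted <- jsd_permutation_test(mk(base_a), mk(base_b), n_perm = 200)
  expect_lt(shifted$p_value, 0.05)
  null <- jsd_permutation_test(mk(base_a), mk(base_a), n_perm = 200, seed = 2)
  expect_gt(null$p_value, 0.05)
})

test_that("differential-splicing post-filter applies both caption clauses", {
  tbl <- tibble::tibble(
    gene_id = rep(c("gA", "gB", "gC"), each = 2),
    transcript_id = paste0("t", 1:6),
    fpkm_a = c(10, 1, 4.9, 2, 10, 2),
    fpkm_b = c(2, 8, 10, 1, 12, 3))
  out <- diff_splice_postfilter(tbl)
  expect_equal(out$gene_id, "gA")  # gB fails FPKM>=5 in a; gC one-sided

  # brute-force agreement on a random table
  set.seed(14)
  big <- tibble::tibble(
    gene_id = rep(sprintf("g%03d", 1:120), each = 3),
    transcript_id = sprintf("t%04d", 1:360),
    fpkm_a = round(runif(360, 0, 12), 2),
    fpkm_b = round(runif(360, 0, 12), 2))
  got <- sort(diff_splice_postfilter(big)$gene_id)
  want <- character(0)
  for (g in unique(big$gene_id)) {
    x <- big[big$gene_id == g, ]
    if (max(x$fpkm_a) >= 5 && max(x$fpkm_b) >= 5 &&
        any(x$fpkm_a > x$fpkm_b) && any(x$fpkm_b > x$fpkm_a)) {
      want <- c(want, g)
    }
  }
  expect_equal(got, sort(want))
})

test_that("PAV labels use strict thresholds", {
  tbl <- tibble::tibble(transcript_id = paste0("t", 1:4),
                        fpkm_a = c(2.5, 2.0, 2.5, 0.05),
                        fpkm_b = c(0.05, 0.05, 0.1, 2.5))
  expect_equal(pav_isoforms(tbl)$pav,
               c("PAV-in-A", "none", "none", "PAV-in-B"))
})

test_that("event ratios are stable under binomial thinning of counts", {
  set.seed(9)
  n_ev <- 300
  true_r <- runif(n_ev, 0.05, 0.95)
  tot <- rpois(n_ev, 400) + 50
  on <- rbinom(n_ev, tot, true_r)
  r_full <- event_ratio(on, tot - on)
  on_thin <- rbinom(n_ev, on, 0.5)
  off_thin <- rbinom(n_ev, tot - on, 0.5)
  r_thin <- event_ratio(on_thin, off_thin)
  expect_gte(stats::cor(r_full, r_thin), 0.95)
})
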