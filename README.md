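# splicescape

Alternative splicing (AS) — the regulated choice among competing splice
sites — produces several transcript isoforms per gene, and in plants the
dominant outcome is intron retention. splicescape is an R package for
researchers who have transcript models and tabular read evidence (isoform
FPKM tables, junction read counts, genotype tables) and want to answer
four questions about them:

1. **What events are there?** Classification of the five classical event
   types between isoforms of a locus — intron retention (IntronR),
   alternative acceptor (AltA), alternative donor (AltD), exon skipping
   (ExonS), alternate terminal exon (AltTE) — plus ORF/reading-frame
   evaluation and nonsense-mediated-decay (NMD) candidacy by the 50-nt
   rule, and evidence filters (junction offset entropy, retained-intron
   coverage, expression/isoform fraction).
2. **How strongly are they used?** Intron-retention ratio (IRR) and
   percent-spliced-in (PSI),

   IRR or PSI = Σ FPKM_on / (Σ FPKM_on + Σ FPKM_off),

   summed over all supporting isoforms, with the standard bounds
   (FPKM ≥ 1, ratio in [0.05, 0.95]), Ward clustering, developmental
   ΔIRR > 0.15 selection, a √JSD (root Jensen–Shannon divergence)
   differential-splicing statistic with post-filters, and
   presence–absence (PAV) calls.
3. **What genetics drives them?** Junction-based splicing-QTL mapping in
   a biparental RIL panel: the splicing frequency y/(y+r) of each
   junction is regressed on marker genotype with a quasi-binomial GLM
   (logit link, Pearson-χ²/df dispersion, t-tests — the overdispersion
   control), Benjamini–Hochberg FDR and a two-fold odds filter for cis
   scans, an interaction model and a modified Bonferroni cutoff (100
   merged regions per chromosome) for trans scans, splice-site SNP
   enrichment in the 12-bp donor/acceptor windows (Yates chi-square),
   and sQTL-to-splicing-gene proximity.
4. **Are they conserved?** Splice anchor sequence tags (SASTs, up to
   300 nt each side of the event's junctions) compared across
   (maize subgenome1, subgenome2, sorghum) ortholog triplets by six-frame
   Smith–Waterman alignment (BLOSUM62, gap 11/1, Karlin–Altschul
   E ≤ 1e-5), yielding a four-way conservation category per event — e.g.
   "conserved between one homeolog and sorghum, lost from the other".

Every input has a seeded synthetic generator with ground-truth labels
(`simulate_genome()`, `simulate_expression()`,
`simulate_junction_evidence()`, `simulate_ril_panel()`,
`simulate_triplets()`), so the whole pipeline runs and validates without
any external data. See `vignettes/splicescape-methods.Rmd` for the models
and the conventions.

## Worked example

```r
library(splicescape)
library(dplyr)

sim    <- simulate_genome(n_genes = 30, seed = 42)
events <- detect_events(sim$exons)
count(events, event_type)
#>   event_type     n
#> 1 AltA           3
#> 2 AltD           9
#> 3 AltTE         18
#> 4 ExonS          2
#> 5 IntronR       22
```

Quantify IRR/PSI across eight developmental stages and select events
whose retention rises by more than 0.15 from day 0 to day 38:

```r
expr   <- simulate_expression(sim, noise_sd = 0.05, seed = 42)
ratios <- event_ratios(events, expr$fpkm)
stage_means <- ratios |>
  inner_join(expr$samples, by = "sample_id") |>
  group_by(event_id, event_type, gene_id, stage) |>
  summarise(on_fpkm = mean(on_fpkm), off_fpkm = mean(off_fpkm),
            ratio = mean(ratio), .groups = "drop") |>
  mutate(sample_id = sprintf("d%02d", stage))
m <- build_ratio_matrix(stage_means, min_fpkm = 0)
delta_ratio_select(m, "d00", "d38")
#>   event_id ratio_a ratio_b delta
#> 1 g0007.e1   0.495   0.775 0.280
#> 2 g0016.e1   0.189   0.499 0.310
#> 3 g0020.e2   0.158   0.426 0.268
#> 4 g0021.e1   0.239   0.516 0.277
#> # 1 more row
```

The selected deltas sit near 0.28–0.31: these are the generator's rising
events (planted rise 0.3) recovered through the full
classify–quantify–filter chain; flat events fall below the 0.15 cutoff.

Map a cis-sQTL in a 105-line RIL panel with a planted 2.5-fold splicing
odds effect (log-odds 0.92) at junction `jx001`:

```r
eff  <- tibble(junction_id = "jx001", beta_cis = log(2.5),
               beta_trans = NA, beta_inter = NA, trans_marker = NA)
rp   <- simulate_ril_panel(n_lines = 105, n_junctions = 10,
                           effects = eff, seed = 42)
scan <- cis_scan(rp$panel, rp$counts, rp$junction_meta)
filter(scan, significant) |>
  select(junction_id, beta, dispersion, p_value, q_value, odds_fold_change)
#>   junction_id   beta dispersion    p_value   q_value odds_fold_change
#> 1 jx001        0.595       4.43 0.00000573 0.0000573             1.81
#> 2 jx004       -0.426       4.12 0.00361    0.0181                1.53
```

The planted junction is recovered decisively (q ≈ 6e-5). The dispersion
of ~4 is the overdispersion the quasi-binomial model absorbs — a plain
binomial test would wildly overstate significance here. In this single
panel the effect estimate (0.60) is attenuated from the planted 0.92 and
one null junction crosses the 5% FDR line — exactly the behavior a 5%
FDR promises on average, which is why the package's calibration checks
run over 200 replicate panels rather than one.

Each result type has a plot method: `autoplot()` on a ratio matrix draws
the Ward-ordered heatmap, `autoplot()` on a cis scan the effect/q
volcano, and `plot_ratio_trajectories()` the stage profiles.
`tidy()`/`glance()` work on quasi-binomial fits.

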