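---
title: "Models and methods behind splicescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splicescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescape)
library(dplyr)
```

splicescape characterizes alternative splicing (AS) from transcript models
and tabular read evidence: it classifies events between isoforms of a
locus, quantifies how strongly each event is used across samples, maps
genetic variation that shifts junction usage in a biparental recombinant
inbred line (RIL) panel, and asks whether events are conserved between
homeologous genes across genomes. This vignette explains the models, the
conventions the package had to pin down where the field's informal
definitions are ambiguous, and what the bundled synthetic-data generators
do and do not emulate.

## Coordinates and transcript models

All internal coordinates are 0-based, half-open; GTF on disk is 1-based
inclusive and converted at the I/O boundary. A transcript model is an
ordered chain of non-overlapping exons on one chromosome and strand; a
splice junction is identified by `(chrom, intron_start, intron_end,
strand)`, with donor and acceptor derived from strand, never stored. The
parser accepts introns down to 1 nt: biological plausibility is the job of
the evidence filters, not the parser. The canonical transcript of a gene
is the longest spliced form, with ties broken lexicographically so the
choice is deterministic.

## Event classification

Five event types are called between isoform pairs and then deduplicated
across all pairs of a gene by (type, affected interval, junction key):

* **IntronR** — an intron of one isoform lies fully inside an exon of the
  other. The retained intron is the affected interval.
* **ExonS** — an internal exon of one isoform is absent from the other
  while both share the bounding donor and acceptor (the skipping isoform
  carries the exact spanning intron).
* **AltA / AltD** — two introns share one splice site and differ at the
  other. Which genomic end is the donor depends on strand. The package
  additionally requires the segment between the competing sites to be
  exonic in the shorter-intron isoform. This constraint is not always
  spelled out in informal definitions but is necessary: without it, every
  skipped exon also scores as one AltA plus one AltD through its shared
  flanking boundaries, and the five classes stop being distinct.
* **AltTE** — at one transcript end, the two isoforms' terminal junctions
  differ and at least one terminal exon has zero exonic overlap with the
  other isoform. Both the 5' and 3' ends are eligible. When both terminal
  exons qualify, the more distal one is reported as the affected
  interval. This is a formalization choice: "alternate terminal exon" is
  used descriptively in assembly pipelines without a decidable rule, and
  this version is decidable from exon chains alone.

Orientation follows one uniform rule: the "on" isoforms are those that
contain the affected interval as exonic sequence — the intron-retaining
isoform for IntronR, the exon-including isoform for ExonS. "Off" isoforms
splice it out. When several isoforms support the same event, all of them
accumulate in the on/off sets, which is what allows ratio quantification
to sum expression over each side.

Events store their defining junction keys: one junction for IntronR (its
single spliced junction — anchors for conservation are taken on both
sides of it), the two flanking introns for ExonS, the two competing
introns for AltA/AltD, and the two differing terminal junctions for
AltTE.

The classifier is validated two ways: against a brute-force enumerator of
containment and shared-boundary relations written independently in the
test suite, over thousands of random isoform pairs; and against
generator-planted events recovered exactly.

## ORFs, reading frame, and NMD

Coding potential is evaluated with a canonical-start ORF finder: if the
isoform carries an ATG at the canonical start offset, translation starts
there; otherwise the longest ATG-initiated ORF is used (ties to the
5'-most). Nonsense-mediated decay (NMD) candidacy applies the classical
50-nt rule, restricted to isoforms that share the canonical start — start
prediction inside assembled isoforms is error-prone, so inherited starts
are the conservative choice. The rule is strict: the stop must sit more
than 50 nt (not 50 exactly) upstream of the last exon–exon junction in
transcript coordinates. Single-exon transcripts are never candidates.

Frame preservation of an event is `affected length mod 3 == 0`; for AltTE
no frame rule is defined (the divergent terminus changes the ORF end
itself), so the package reports `NA` rather than guessing. Under
stochastic splicing — affected lengths uniform over a wide range — one
third of events preserve frame, a null the test suite checks against
100,000 simulated lengths.

Region assignment (`CDS`, `UTR5`, `UTR3`, `noncoding`) compares the
affected interval with the canonical CDS genomic span. Any overlap with
the span counts as CDS — deliberately including retained introns that sit
between coding exons, which disrupt the coding sequence even though the
intron itself is not annotated CDS. Only events strictly outside the span
are UTR, assigned strand-aware.

## Evidence filters

Three filters decide which isoforms are trustworthy:

* **Junction entropy** — Shannon entropy (bits) of the distribution of
  junction-spanning read alignment offsets. Reads piled at a single
  offset are an alignment artifact (entropy 0); genuine junctions spread
  over many offsets. The threshold is strict: entropy must exceed 2 bits,
  so a uniform spread over exactly four offsets (2.0 bits) fails.
* **Retained-intron coverage** — the informal requirement "median
  coverage of 10 over at least 90% of the intron" admits two readings, so
  the filter evaluates both and requires both: the median per-base depth
  must reach 10 *and* at least 90% of bases must individually reach
  depth 10. Both sub-verdicts are reported separately so users can relax
  either. Retention percentage is `100 b / (b + s)` with `b` the
  boundary-spanning and `s` the spliced-junction reads, and must reach
  10%. This b/(b+s) form is the package's own definition, isolated in one
  function, since the cited upstream tools do not print a formula.
* **Expression/fraction** — an isoform is accepted if in at least one
  sample it reaches FPKM 1 and 5% of its gene's total FPKM.

## Splicing ratios (IRR / PSI)

For IntronR and ExonS events the usage ratio is

$$\mathrm{IRR\ or\ PSI} = \frac{\sum \mathrm{FPKM}_{on}}{\sum
\mathrm{FPKM}_{on} + \sum \mathrm{FPKM}_{off}}$$

summed over all supporting isoforms on each side. Ratio matrices keep
only events whose combined on+off FPKM reaches 1 in every sample and
whose ratio stays within [0.05, 0.95] in every sample — outside those
bounds the event is effectively constitutive and the ratio mostly
measures noise. Drop reasons are attached to the matrix so filtering is
auditable.

Stage profiling selects events whose ratio rises by strictly more than
0.15 between two stages. Clustering uses Ward's minimum-variance method
on Euclidean distances after a `log(x + 1e-6)` transform (`stats::hclust`
with `ward.D2`; the test suite re-derives the merge heights through the
Lance–Williams recursion). The epsilon is the package's choice; any value
far below the 0.05 ratio floor gives the same ordering. Expression shifts
between stages use an equal-variance two-sided t-test on `log(FPKM +
1e-6)` — log because FPKM are approximately log-normal; the degenerate
zero-variance case is defined explicitly (t = 0, p = 1 for identical
means) rather than erroring.

Gene-level differential splicing between two conditions is scored by the
square root of the Jensen–Shannon divergence (log base 2) between the
mean isoform-fraction vectors — a bounded metric on [0, 1] from the same
statistic family as the assembly-pipeline splicing tests it replaces —
with a label-permutation p-value (seeded, 1000 permutations by default).
Calls are post-filtered to genes with at least one isoform at FPKM ≥ 5 in
each condition and at least one isoform more abundant in each condition,
so one-sided expression shifts do not masquerade as splicing changes.
Presence–absence (PAV) isoforms are those strictly above 2 FPKM in one
sample and strictly below 0.1 in the other. All inequalities printed as
strict are implemented strict.

## Splicing QTL mapping

For a junction in a RIL panel, the splicing frequency of line $i$ is
$y_i / (y_i + r_i)$: junction-spanning reads over all reads of the
containing gene. Normalizing by the gene removes expression differences
and reference-allele alignment bias from the splicing signal. Junctions
enter the scan with at least 20 total spanning reads and 5 per line on
average.

Counts are overdispersed relative to binomial sampling (line effects,
library effects), so tests use a quasi-binomial GLM: logit-link binomial
regression with dispersion $\hat\varphi$ estimated as Pearson
$\chi^2/(N-k)$ and coefficient t-tests on $\sqrt{\hat\varphi}$-scaled
standard errors (R's `glm`, `quasibinomial` family). The synthetic truth
model is beta-binomial with intraclass correlation $\rho = 0.05$ — the
analysis model is deliberately mis-specified the way real analyses are,
and the test suite checks that the type-I error at $\alpha = 0.05$ stays
within [0.03, 0.07] under that truth, which is the entire point of the
overdispersion control. Complete separation is detected and handled by a
Haldane-style pseudo-count refit (y + 0.25, n + 0.5), flagged in the
result.

The cis scan tests the genotype of the marker segment containing the
junction (genotypes coded B = 0, M = 1, so positive effects are
"up-regulated in M"), applies Benjamini–Hochberg FDR across junctions,
and annotates a two-fold splicing-odds filter
($e^{|\hat\beta|} \ge 2$). The trans scan tests each marker on other
chromosomes with the interaction model
$\mathrm{logit}(p) = \beta_0 + \beta_1 G_{cis} + \beta_2 G_{trans} +
\beta_3 G_{cis} G_{trans}$, reporting the trans main effect and the
interaction separately — the interaction captures effects present under
only one cis background. Because trans tests are numerous and markers
within a chromosome are correlated, the significance cutoff uses a
modified Bonferroni: each chromosome is cut into 100 equal-bp regions,
markers within a region count once, and the cutoff is 0.05 divided by
the junction-summed count of occupied regions on other chromosomes.
"Equal-sized" is read as equal base pairs. Every marker is still tested;
the merging affects only the cutoff. Missing genotypes drop the line from
that test (complete-case) rather than being imputed.

Splice-site polymorphism enrichment uses the strand-aware 12-bp windows
around each junction: 9 bp at the donor (3 exonic + 6 intronic,
consensus CAG|GURAGU) and 3 bp at the acceptor (2 intronic + 1 exonic,
AG|G). The donor-window anchoring is a convention derived from that
consensus. Enrichment of window SNPs in significant junctions versus the
rest is tested with the Yates-corrected chi-square (closed form,
cross-checked against `chisq.test` in the suite). Proximity of trans-sQTL
to known splicing-related genes is a plain interval question: the
fraction of sQTL with any such gene within a 1 or 10 Mb flank.

## Conservation across genomes

For each event, splice anchor sequence tags (SASTs) are built: up to
300 nt of genomic sequence on each side of the event's defining junction
span, truncated at the gene boundaries (not contig boundaries) to avoid
picking up intergenic homology, and reverse-complemented on the minus
strand so anchors read in transcription orientation.

Anchors of same-type events are compared between the members of a
(maize1, maize2, sorghum) triplet by translated local alignment: all 6x6
reading-frame pairs, Smith–Waterman with BLOSUM62, gap open 11 / extend
1, best frame pair kept. E-values use Karlin–Altschul statistics
$E = K m n e^{-\lambda S}$ with the gapped BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$ and the nucleotide search space
$m \times n$ — a simplification of the per-frame search spaces that is
conservative at anchor scale. A pair matches at $E \le 10^{-5}$, relaxed
to $10^{-2}$ when both anchors are shorter than 100 nt (the relaxation
value itself is the package's choice; short anchors cannot reach
astronomical scores). Calls whose aligned span is below 30 nt in at
least two members are discarded.

Matched events classify into four categories: (1) conserved in maize1,
maize2 and sorghum (both maize–sorghum pairs match; a maize1–maize2 match
is not additionally required); (2) maize1–sorghum only, with no same-type
event in maize2; (3) maize2–sorghum only, with none in maize1; (4)
maize1–maize2 with no same-type event in sorghum. Categories 2 and 3 are
the evolutionarily interesting ones: an event shared with the outgroup
but missing from one homeolog is most parsimoniously an event lost after
whole-genome duplication. Summaries count clusters (one per matched call
within a triplet and event type), member events, and distinct genes.
Swapping the maize1/maize2 labels provably swaps categories 2 and 3 and
fixes 1 and 4; the suite asserts this exactly.

## Synthetic data: what it emulates, and what it does not

Every input the pipeline consumes has a seeded generator, and all
generators are pure functions of their arguments — same seed, same bytes.

* `simulate_genome()` plants genes of 2–12 exons (exons 50–400 nt,
  introns 60–3000 nt) with up to three alternative isoforms, each
  carrying exactly one event; type frequencies default to the rank order
  typical of plant transcriptomes (intron retention ~0.47 most common,
  exon skipping ~0.05 rarest). Each alternative isoform perturbs a
  distinct structural element of the gene so planted events never
  collide. The AltTE plant shifts both the shared-exon boundary and the
  terminal junction so the planted pair cannot simultaneously satisfy
  the AltA shared-donor relation.
* `simulate_expression()` produces staged FPKM tables (default: eight
  stages across days 0–38 of seed development, three replicates). Events
  in single-alternative genes get either flat ratios or a planted rise of
  exactly `delta` (default 0.3) along a normalized logistic; rising
  events optionally decay in expression, emulating the negative coupling
  between intron retention and expression during seed development. At
  `noise_sd = 0` realized ratios equal planted ratios to machine
  precision, which anchors the exactness tests.
* `simulate_junction_evidence()` spreads genuine junction reads
  multinomially over 45 alignment offsets and piles artifact reads at a
  single offset; retained introns get Poisson per-base coverage at 20x
  with a 30% retention fraction, non-retained introns 1x and 2%. 20x is
  chosen so the dual depth rule (median and 90%-of-bases) is reliably
  met by true positives even for the shortest (60 nt) introns, where
  Poisson fluctuation at marginal coverage would otherwise fail the
  90% clause a nontrivial fraction of the time.
* `simulate_ril_panel()` draws 105-line mosaic genotypes by Markov
  switching over equal-bp marker segments, beta-binomial junction counts
  ($\rho = 0.05$, ~50 gene reads/line) around planted cis/trans/
  interaction log-odds effects, and SNPs enriched in the splice windows
  of designated junctions.
* `simulate_triplets()` copies an ancestral gene (with one event) into
  three genomes with independent per-copy substitutions (no indels, so
  coordinates stay comparable) and deletes the alternative isoform from
  the member excluded by the planted category.

What passing these tests shows: the implementation computes its own
definitions correctly, the statistical machinery is calibrated under
realistic overdispersion, and the conservation logic recovers planted
history under divergence comparable to the maize–sorghum split. What it
does not show: robustness to assembly artifacts, alignment bias,
fragmented annotations, indel divergence between genomes, or
non-uniform read coverage — none of which the generators emulate. Real
transcriptome catalogs also contain single-exon genes, overlapping genes
and trans-spliced oddities that the generators deliberately avoid.

## Numerical choices and degenerate inputs

* Strict inequalities wherever a threshold is printed as strict
  (entropy > 2, delta > 0.15, PAV > 2 / < 0.1, NMD > 50 nt).
* `log(x + 1e-6)` before clustering and t-tests; epsilon far below every
  ratio/FPKM floor in use.
* Ratio of an event with zero on+off expression is undefined (`NA`), and
  lines with zero gene reads are dropped from sQTL fits, not imputed.
* Ties in the canonical-transcript and longest-ORF choices break
  deterministically (lexicographic id; 5'-most start).
* Ward clustering of a constant matrix is a valid degenerate tree (all
  merge heights 0); two rows merge at their Euclidean distance.
* The quasi-binomial fit refuses designs with fewer informative lines
  than coefficients plus two, and caps IRLS at 100 iterations.

## Problem sizes used in validation

The packaged validation runs at desk scale, chosen so the full suite
exercises every code path with tight statistical bands: 100,000 simulated
event lengths for the frame null; 1,000 random isoform pairs against the
brute-force classifier oracle; 10,000 random ratio records against
brute-force filters; 200 replicate RIL panels (100 lines, 11 junctions
each) for sQTL calibration, power and effect recovery; 200 triplets per
divergence level (2% and 10% per copy) for conservation recovery; 500
events for thinning stability. These sizes are statements of the
validation design, not of the method's limits — all functions operate on
arbitrarily larger tables.

## Known limitations

* Events are called pairwise and deduplicated, not from a splice graph;
  a gene with three acceptors for one donor yields pairwise-deduped
  events, and counts can differ from graph-based callers.
* PSI here is exon-skipping inclusion from isoform abundances, not
  junction-count PSI; the two agree only when isoform quantification is
  accurate.
* The E-value constants assume gapped BLOSUM62 statistics regardless of
  anchor composition; for anchors under ~60 nt the relaxed threshold is
  doing most of the work.
* The trans scan fits one junction x marker model at a time; polygenic
  trans architecture and linkage between trans markers are not modeled.
* NMD prediction is rule-based (50-nt); it does not model UTR introns'
  special cases or long 3' UTR triggers.
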