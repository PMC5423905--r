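Package: splicescape
Title: Alternative Splicing Event Classification, Quantification, and
    Genetic Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing alternative splicing from transcript
    models and tabular read evidence: classification of the five classical
    event types (intron retention, alternative acceptor, alternative donor,
    exon skipping, alternate terminal exon) between isoforms of a locus,
    ORF and nonsense-mediated-decay prediction with the 50-nt rule,
    junction-entropy and intron-coverage evidence filters, intron-retention
    ratio (IRR) and percent-spliced-in (PSI) quantification with Ward
    clustering and developmental-stage profiling, junction-based splicing-QTL
    mapping in biparental recombinant inbred panels using quasi-binomial
    generalized linear models with overdispersion control, and cross-genome
    conservation calling of splicing events between homeologous genes via
    translated local alignment of splice anchor sequence tags. Includes
    seeded synthetic-data generators that emulate every input the pipeline
    consumes, with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    withr,
    generics,
    ape,
    igraph,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
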