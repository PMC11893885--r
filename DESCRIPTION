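Package: enhdyn
Title: Enhancer Discovery and Enhancer-Promoter Interaction Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transcribed-enhancer discovery and
    enhancer-promoter interaction dynamics across a three-timepoint neuronal
    differentiation time course. Calls bidirectionally transcribed loci
    (putative enhancers) from stranded CAGE/NET-CAGE transcription start site
    signal, quantifies and clusters temporal expression with a negative
    binomial ANOVA-like test, calls significant chromatin interactions from
    Capture Hi-C valid pairs against an empirical negative-control background,
    quantifies interactome rewiring with per-node Jaccard and overlap
    coefficients, tests GWAS-variant enrichment in enhancer sets with
    LD expansion and matched-control permutations, and characterizes
    regulatory regions by conservation, SNP density and nucleotide diversity.
    Ships a synthetic-data generator with planted ground truth so every stage
    is testable without external downloads.
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
    readr,
    ggplot2,
    generics,
    MASS,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    igraph,
    yaml,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
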