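Package: lincPipe
Title: Identification and Co-Expression Target Analysis of Long Intergenic
    Noncoding RNAs from Assembled Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for discovering long intergenic
    noncoding RNAs (lincRNAs) from an assembler-merged transcript set and
    characterising their regulatory context. Implements the six-step
    identification cascade (intergenic class code, size, coding potential,
    protein-domain and protein-homology screens, expression floor),
    novel-versus-known classification and feature characterisation,
    two-group differential expression on FPKM with Benjamini-Hochberg
    control, cis (genomic window) and trans (expression correlation)
    potential-target-gene prediction, signed lincRNA-target direction
    tallies and network summaries, hypergeometric over-representation
    analysis, and cross-dataset correlation validation. A seeded synthetic
    study generator with full ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    NetworkInference, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'coding-potential.R'
    'diffexp.R'
    'enrich.R'
    'identify.R'
    'lincPipe-package.R'
    'transcript-model.R'
    'simulate.R'
    'targets.R'
    'pipeline.R'
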