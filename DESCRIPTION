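Package: ancientpop
Title: Ancient-DNA Authentication and Population-Genomic Admixture Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing a single ancient genome against modern
    population panels: sample-authenticity diagnostics (contamination
    estimation from diagnostic SNPs, sex inference from X/autosome depth,
    fragment-length and terminal-deamination profiles), variant
    classification and tabulation, ABBA/BABA D-statistic and f3
    three-population admixture tests with weighted block-jackknife
    standard errors, a windowed HKA-style selection scan with FDR
    control, a cross-taxon fixation filter for candidate
    post-domestication variants, and synthetic-data generators with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
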