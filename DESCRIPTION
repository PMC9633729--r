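Package: riboscreen
Title: Ribosome Profiling Differential Translation and Rescue-Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing matched RNA-seq and ribosome-profiling (Ribo-seq)
    experiments across a four-condition knock-out/knock-down rescue design.
    Provides footprint read pre-processing (quality filtering, UMI-aware
    duplicate collapsing, adapter trimming, footprint size selection), a
    simplified negative-binomial Wald test for differential abundance with
    median-of-ratios normalization and Benjamini-Hochberg correction,
    translation-efficiency event classification, a three-criterion
    rescue-based target screen, gene-set overlap and motif-instance
    enrichment, per-nucleotide footprint coverage with a windowed
    ribosome-accumulation test, and seeded synthetic-data generators with
    ground-truth tables for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea,
    jsonlite
Config/testthat/edition: 3
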