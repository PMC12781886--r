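Package: coldsplice
Title: Kinetic Dissection of Cold-Induced Transcriptional Repression at FLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Steady-state kinetic models and Bayesian inference tools for
    dissecting cold-induced transcriptional repression of the Arabidopsis
    floral repressor FLC. Provides closed-form models of intronic RNA
    profiles (nascent plus lariat contributions), a two-species
    spliced/unspliced system for splicing-rate estimation, exponential
    mRNA-decay models with correction for qPCR normalisation bias, a
    single-ellipsoid nested-sampling engine for posterior inference and
    Bayes-factor model comparison, NET-seq termination-index and PolII
    elongation-rate analytics, and synthetic-data generators emulating
    qPCR tiling profiles, transcription-inhibition decay courses, smFISH
    cell tables and strand-specific nascent-transcript coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
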