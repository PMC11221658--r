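Package: lncage
Title: Minimal Evolutionary Age Classification of Long Noncoding RNAs by
    Reciprocal Positional Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies long noncoding RNA (lncRNA) loci into minimal
    evolutionary age (MA) groups by reciprocal positional (syntenic)
    conservation across species. Provides a consensus coding-potential rule
    combining three calculator calls with an open-reading-frame flag,
    thresholded coordinate lifting over UCSC alignment chains with
    minMatch/minBlocks semantics, transposable-element masked and retained
    homology passes, oldest-age merging with public synteny annotations,
    per-gene genomic feature metrics (TPM, exon/intron structure, splice
    motif strength, TE content, expression matching), and the enrichment
    statistics used downstream (one-sided hypergeometric tests with FDR
    control, promoter TF analyses against a shuffled null, module
    preservation verdicts). A seeded synthetic multi-species data generator
    with planted ground truth makes the whole pipeline testable end-to-end
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
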