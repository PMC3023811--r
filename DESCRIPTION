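Package: tempro
Title: Temporal Expression Profiling of Sensory Precursor Lineages
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for temporal expression profiling of sorted neural
    precursor cell populations: trusted-gene probe-set filtering, moderated-t
    differential expression between marker-positive and marker-negative cells
    at successive timepoints with Benjamini-Hochberg FDR control and
    fold-change gating, Venn partitioning of temporal gene lists, gene-set
    over-representation with plain and EASE-corrected one-sided Fisher exact
    tests, strand-aware IUPAC consensus motif scanning of promoter windows
    (X boxes, E boxes and related bHLH sites), resampling null distributions
    with z-tests for list-level enrichment, and a wild-type versus mutant
    fold-change screen for candidate proneural target genes. A synthetic-data
    module generates complete studies with planted ground truth for
    benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
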