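Package: seqscout
Title: Headless Coverage Profiling, Region Quantification and Lightweight
    Differential Expression for RNA-Seq Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A scriptable compute layer for exploratory bulk RNA-Seq
    analysis. Manages dataset manifests of BAM/BigWig-backed samples grouped
    by biological condition, extracts and condition-averages coverage
    profiles over genes or arbitrary genomic regions, counts reads over
    gene exon unions and custom (possibly non-annotated) regions with
    median-of-ratios normalization and RPKM scaling, performs two-group
    differential expression with negative-binomial and Welch tests joined
    by p-value combination (Fisher, Simes, weighted), and provides
    correlation, hierarchical clustering, PCA and classical MDS on any
    expression table. Ships a deterministic synthetic-dataset generator
    (genome, GTF, BAM, BigWig, truth tables) so the whole pipeline is
    testable offline, plus a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ape,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
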