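Package: coreGRN
Title: Core Regulator Discovery and K-Core Hierarchy in Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds integrated transcription-factor and microRNA regulatory
    networks from interaction evidence (ChIP peak to TSS assignment, multi-database
    miRNA target consensus), ranks candidate core regulators with eight strategies
    (differential expression, degree, target fold enrichment, closeness, betweenness,
    pagerank, K-core), organizes regulators into a K-core layered hierarchy, and
    evaluates how well the selected regulators explain up/down gene expression with
    linear regression, principal component, and support vector models under
    cross-validation. Includes degree-preserving edge randomization and typed
    node-sampling nulls, a tissue-specificity (SPM) statistic, and a synthetic
    network generator with planted core regulators for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    e1071,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
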