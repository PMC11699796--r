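Package: fermtrans
Title: Subpopulation Transcriptomics of Yeast Wine Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for subpopulation-resolved bulk RNA-seq of
    wine-fermenting yeast. Provides a simplified negative-binomial Wald
    engine for one-vs-rest differential expression with median-of-ratios
    normalization, cluster-specific transcriptomic signature (CSS) calling,
    quantitative-trait-transcript (QTT) regression of expression on lactic
    acid with principal-component and surrogate-variable correction,
    Spearman correlation networks around focal genes, hypergeometric
    gene-set enrichment with accumulated fold-change summaries, end-point
    metabolite correlations, and a seeded synthetic-data generator with
    ground truth for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
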