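Package: emtscape
Title: EMT Scoring and Immune Landscape Analysis for Tumor Single-Cell
    RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies epithelial-mesenchymal transition (EMT) states in
    tumor single-cell RNA-seq data with three harmonized scoring metrics
    (the 76-gene signature method, a signed two-sample Kolmogorov-Smirnov
    score, and a multinomial-regression expected-class score), places
    pseudobulk profiles onto a bulk reference panel by joint gene-wise
    z-scaling, and relates the EMT spectrum to the tumor immune
    microenvironment through marker-based annotation, composition trend
    tests, dot-plot statistics, and rank-based (Wilcoxon-Mann-Whitney)
    gene-set enrichment. Ships a negative-binomial synthetic
    tumor-microenvironment generator with known ground truth so that the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    methods,
    nnet,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
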