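Package: scatlaskit
Title: Reusable Building Blocks for a Fetal Lung Single-Cell Atlas Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the bespoke computational steps used to build a
    multi-sample single-cell RNA-seq cell atlas as tested, reusable
    functions: log-CP10K normalization, boundary-exact quality-control
    filtering, per-sample dispersion-based feature selection with a
    cross-sample union, control-bin gene-signature scoring, one-vs-rest
    Wilcoxon marker ranking with out-group-fraction and fold-change
    filters, cluster-level doublet flagging (DouCLing), and cell-type
    composition bias statistics (chi-squared, per-type Fisher exact with
    Benjamini-Hochberg correction, and weighted developmental-stage /
    proximal-representation coordinates). Includes a negative-binomial
    multi-sample simulator with planted doublet clusters and composition
    gradients so every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
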