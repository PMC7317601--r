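Package: coexhub
Title: Co-Expression Network Hub-Gene Discovery with Meta-Analysis and
    Marker Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for nominating hub genes from
    multi-study gene expression data. Builds weighted gene co-expression
    networks from first principles (absolute-correlation similarity,
    soft-threshold adjacency, topological overlap, dynamic branch
    cutting, module eigengenes, module-trait correlation and
    module-membership / gene-significance screening), pools per-study
    standardized mean differences with fixed and DerSimonian-Laird
    random-effects models including Cochran's Q, I-squared and Egger's
    funnel-asymmetry test, filters scored interaction networks by
    confidence and node degree, and evaluates candidate markers by
    ROC/AUC, Kaplan-Meier / log-rank survival comparison and
    hypergeometric over-representation analysis. Ships a synthetic-data
    module that plants known modular, meta-analytic, network and
    survival structure so every stage is testable end-to-end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    mclust,
    metafor,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
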