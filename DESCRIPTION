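Package: oastrat
Title: Stratification of Osteoarthritis Cartilage Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to stratify bulk RNA-Seq cohorts into molecular
    subgroups. Provides negative-binomial count simulation with planted
    subgroup structure, size-factor normalisation and Wald differential
    expression with Benjamini-Hochberg control, graph-regularised
    non-negative matrix factorisation with consensus clustering and
    silhouette-based model selection, nearest shrunken centroid gene-panel
    derivation with a cross-validated linear support vector machine,
    hypergeometric gene-set over-representation, active-subnetwork
    detection with a permutation null, and secreted-protein biomarker
    reporting. A single seeded pipeline runs all stages end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
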