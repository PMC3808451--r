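Package: pleionet
Title: Directed Epistasis Networks from Pleiotropy in Multi-Phenotype Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers directed, signed variant-to-variant influence networks
    from experimental cross data with two or more quantitative phenotypes.
    Phenotypes are decomposed into orthogonal eigentraits by singular value
    decomposition; exhaustive two-locus regressions are fitted per eigentrait;
    the per-eigentrait interaction coefficients are reparametrized into two
    directed influence coefficients with delta-method standard errors; and
    significance is assessed against pooled permutation null distributions
    with Holm, Benjamini-Hochberg, or local false discovery rate correction.
    Includes a reader/writer for the R/qtl "csv" cross format, a backcross
    simulator with known ground truth for validation, network export
    (adjacency, edge list, GraphML), and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
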