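Package: crossclr
Title: Cross-System Transcriptional Network Inference and Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis chain for comparing chemically perturbed in vitro and
    in vivo liver transcriptomes: intensity flooring, per-chip and per-gene
    normalization, present-flag and sample-correlation quality filters,
    dose-series ANOVA and two-group t-test differential-expression filters
    with max-pairwise fold change, Pearson/average-linkage hierarchical
    clustering of condition-averaged profiles, context likelihood of
    relatedness (CLR) gene-regulatory-network inference with B-spline
    mutual-information estimation, cross-system network intersection to
    extract conserved regulatory subnetworks, hypergeometric gene-set
    over-representation, and a synthetic-data generator that plants
    two-system regulatory networks with a conserved core so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
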