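Package: fcnet
Title: Graph-Theoretical Analysis of Resting-State Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Pearson correlation networks from parcellated resting-state
    fMRI time series, thresholds them over a sparsity grid, computes global and
    nodal topological metrics (clustering, path length, efficiency, betweenness,
    degree) with small-world normalization against degree-preserving rewired
    null ensembles, integrates every metric across thresholds by the area under
    the curve, quantifies intra- and inter-module connection densities over a
    six-module anatomical parcellation, and compares groups with
    covariate-adjusted ANCOVA, LSD post hoc tests, Bonferroni and
    false-discovery-rate corrections. Includes a synthetic-cohort generator
    with block-modular covariance and plantable group effects so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
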