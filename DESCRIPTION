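Package: ecoclines
Title: Phylogenetic Two-Block Partial Least Squares and Multivariate
    Spatial Clines for Ecogeographic Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for multivariate ecogeographic analysis of linear
    morphometric measurements: ordinary and phylogenetic two-block
    partial least squares between an environmental and a morphometric
    block, reduced-rank regression of a trait block on latitude and
    longitude to estimate multivariate spatial clines, expectation-
    maximization imputation of missing measurements under a
    multivariate-normal model, and Mantel permutation tests of
    isolation by distance on geodesic versus phenotypic distance
    matrices. Phylogenetic variants weight species by the Brownian-
    motion covariance implied by a time-scaled phylogeny via
    generalized least squares. Includes a synthetic-data generator
    (pure-birth trees, Brownian trait evolution with planted low-rank
    cross-block coupling, specimen-level sex effects, spatial clines,
    isolation-by-distance drift and missing-at-random gaps) so every
    pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
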