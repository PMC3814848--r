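Package: devconnectome
Title: Developmental Analysis of Weighted White-Matter Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction and graph-theoretical analysis of weighted
    structural brain networks across developmental age groups.
    Builds per-subject connectomes from fiber-count and fractional-anisotropy
    tables (edge weight FN*FA normalized by mean regional volume, with a
    fiber-count threshold), extracts group-level backbone networks by an
    exact one-tailed sign test with Bonferroni correction, computes weighted
    graph metrics (strength, Onnela clustering, harmonic path length, global,
    local and nodal efficiency), evaluates small-worldness against
    degree-preserving Maslov-Sneppen null ensembles, detects modules by a
    size-normalized greedy agglomeration of weighted Newman modularity with
    participation coefficients and hub classification, and compares adjacent
    age groups with a general linear model including age and sex covariates
    and false-discovery-rate correction of nodal maps. A synthetic cohort
    generator with planted modular structure makes the whole pipeline
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
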