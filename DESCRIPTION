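Package: trialscape
Title: Mapping and Collaboration-Network Analysis of Clinical-Trial Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the global landscape of industry- and
    non-industry-sponsored clinical trials from registry metadata. Parses and
    classifies trial records, computes per-country trial densities and
    sponsorship and internationality shares, builds country-country
    collaboration networks from the binary trial-by-country incidence matrix,
    tests collaborations for overrepresentation against a fixed-margin
    (curveball) permutation null model, quantifies a degree of
    overrepresentation, and partitions the resulting co-occurrence networks
    with a two-level map-equation community-detection algorithm. Includes a
    synthetic registry generator with plantable collaboration blocks so the
    full pipeline can be exercised and validated without registry access.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    igraph,
    methods,
    jsonlite,
    Matrix,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    optparse,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
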