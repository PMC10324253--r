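Package: amendr
Title: Active Module Identification from Paired Differential Expression
    Contrasts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts a single connected, high-scoring "active module"
    from a protein-protein interaction network by combining the
    equivalent change index (ECI) -- a per-gene measure of equivalent or
    inverse regulation between two differential-expression contrasts --
    with coreness-normalized random walk with restart and a heuristic
    maximum-weight connected subgraph solver, applied iteratively under
    an exponentially decaying filtering-rate schedule.  Includes module
    evaluation statistics (hypergeometric overrepresentation, the
    empirical-to-hypergeometric ratio under permutation nulls, Jaccard
    and nested consistency indices with bootstrap significance), a
    synthetic planted-module generator for end-to-end validation, and
    readers for edge-list, GraphML, STRING-links and GMT formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
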