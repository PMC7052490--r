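Package: metaroutr
Title: Expression-Weighted Metabolic Route Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a directed metabolic network from a reaction table and a
    gene-expression cohort, with compounds as nodes and enzyme-catalysed
    reactions as expression-weighted edges, then enumerates and ranks simple
    routes between two compounds. Currency metabolites (ATP, H2O, ...) are
    excluded as intermediates, unexpressed enzymes (cohort mean below 1) are
    removed, and parallel edges between the same compound pair are collapsed
    to the enzyme with the highest mean expression. Routes are ranked by a
    bottleneck criterion (maximise the minimum edge weight) or a stability
    criterion (minimise the standard deviation of edge weights), and enzymes
    can be flagged up- or down-regulated in a user cohort by fold change
    against the reference. Includes a synthetic fixture generator with
    planted-pathway benchmarks and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    tidyr,
    readr,
    rlang,
    stringr,
    igraph,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
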