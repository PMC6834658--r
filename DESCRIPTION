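Package: n2kprior
Title: Prioritising Updates to Protected-Area Target-Species Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for gap analysis and spatial prioritisation of
    target-species list updates across a protected-area network such as
    Natura 2000. Cross-tabulates species by taxon, IUCN Red List status and
    directive listing; builds per-site candidate-species pools (declared
    targets plus a bounded number of additions, habitat-sharing species
    first); solves the minimum-set reserve-selection problem with a
    simulated-annealing optimiser using a species-penalty-factor objective
    (with greedy and exhaustive back-ends as baselines and oracles); and
    summarises bootstrap replicates into site and species-by-site selection
    frequencies with richness-independence and concentration diagnostics.
    Includes a synthetic-data generator emulating the statistical structure
    of the real inputs, and readers and writers for Marxan-dialect input
    files.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
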