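Package: cophymap
Title: Space-Reduced Node Mapping for the Dated Tree Reconciliation Problem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cophylogeny mapping of a parasite phylogeny into a dated host
    phylogeny under the four-event model (codivergence, duplication, host
    switch, loss). Implements a bottom-up node-mapping solver for the dated
    tree reconciliation problem that stores per-parasite-node lists of
    mapping sites instead of a dense cost matrix, retaining one optimal
    codivergence/duplication site and the most recent feasible host switch
    per direction, so that reported maps are optimal and time-consistent
    while the table grows sub-quadratically for realistic (Yule- to
    PDA-shaped) trees. Includes Yule and Uniform tanglegram simulators,
    naive full-table and exhaustive reference solvers used as correctness
    oracles, the closed-form complexity model (site-count recurrence and
    closed form, level thresholds, expected level profiles, space-bound
    sums, tree-space integrals, mapping-site memory arithmetic), and a
    power-law least-squares fitter for empirical space profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
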