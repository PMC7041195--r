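Package: paretoKnock
Title: Exact Bi-Objective Knockout Design for Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact multi-objective mixed-integer strain design for
    constraint-based metabolic models. Computes Pareto frontiers of competing
    flux objectives (typically product formation versus biomass growth) under a
    fixed number K of reaction knockouts, then exhaustively enumerates all
    equivalent knockout sets per frontier point via no-good cuts, optionally
    restricted to the sets whose mutant flux state is Manhattan-closest to a
    wild-type reference (linearised MOMA). Includes flux balance analysis,
    single-knockout screens, a SimpleOptKnock comparator, readers for SBML
    Level 3 FBC v2 and a documented JSON model dialect, deterministic toy
    network generators with brute-force oracles, and a reproducible
    command-line pipeline. All programs are solved exactly with a built-in
    bounded-variable simplex and branch-and-bound core.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    xml2,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    boot,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'model-core.R'
    'fba.R'
    'pareto.R'
    'enumeration.R'
    'fixtures.R'
    'paretoKnock-package.R'
    'pipeline.R'
    'solver.R'
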