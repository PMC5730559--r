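Package: gpdi
Title: General Pharmacodynamic Interaction Modeling for Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, maximum-likelihood estimation, and classification of
    directional pharmacodynamic interactions between two or more drugs on
    checkerboard combination data. Single-drug exposure-response is described
    by sigmoidal Emax (Hill), linear slope, or power models; interactions are
    captured by saturable perpetrator-concentration-dependent shifts of a
    victim drug's PD parameters (EC50 or Emax), composable under Loewe
    Additivity (implicit dose-substitution equation solved by root finding),
    Bliss Independence, simple effect addition, or highest single agent.
    Includes a lag-plus-logistic growth model for longitudinal optical-density
    read-outs, conventional comparator models (Greco interaction index,
    empiric Bliss, isobole curvature score), a stepwise likelihood-ratio model
    building procedure, Fisher-information design identifiability analysis,
    sham-combination additivity margins, six-way interaction classification,
    and construction of directed perpetrator-victim interaction networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
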