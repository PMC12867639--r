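Package: asympgg
Title: Asymmetric Public Goods Games: Equilibria, Learning Dynamics, and Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for repeated public goods games among players with unequal
    endowments and productivities. Implements linear and threshold (step) reward
    functions, exhaustive one-shot Nash enumeration and Folk-theorem
    characterization of subgame-perfect equilibrium payoffs, deterministic
    reactive strategies, an introspection-dynamics learning model with
    inequity-averse utility (aversion to unequal absolute and relative
    contributions), the outcome statistics used in behavioral experiments
    (group relative contribution, group overall surplus, success rate, Gini
    coefficient, lag-1 reciprocity), a synthetic round-level data generator,
    and grid-search fitting of the learning model to observed group surplus.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
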