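Package: metaheur
Title: Metaheuristics for Global Optimization in Systems Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derivative-free global optimization for the problem classes that
    dominate computational biology: enhanced scatter search (eSS) for
    continuous and mixed-integer nonlinear programs, variable neighbourhood
    search (VNS) for integer programs, a deterministic cooperative strategy
    that runs several heterogeneous solver threads and exchanges incumbents at
    a fixed evaluation interval, and a multi-start Metropolis-Hastings sampler
    for Bayesian parameter estimation. Ships ready-made application objectives:
    training Boolean logic models of signalling networks against perturbation
    data, flux-balance-analysis gene-knockout strain design on a toy central
    carbon metabolism model, the gear-train integer design benchmark, and a
    registry of classic continuous test functions with shifted and rotated
    variants. All solvers are seeded and reproducible, account for every
    objective evaluation, and emit tidy convergence histories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    generics,
    graphics,
    jsonlite,
    lhs,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
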