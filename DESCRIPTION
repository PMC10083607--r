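Package: replicells
Title: Agent-Based Simulation of Protocell and Genetic-Element Coevolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-round, agent-based simulation of populations of protocells
    (reproducers) that feed on a shared resource pool, pay a housekeeping cost,
    and divide stochastically once their resource balance exceeds a threshold,
    coupled to an intracellular birth-death process of autonomous and
    nonautonomous genetic elements (replicators) executed as propensity-sampled
    elementary events. Provides the analytic equilibrium and trade-off formulas
    for the protocell-only model, the deterministic consumer-resource limit of
    the element-level kinetics with its equilibrium classification, three
    division scenarios with closed-form mutualist-only daughter probabilities,
    and ensemble experiment runners for competition trajectories, trade-off
    heatmaps and division-scenario phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
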