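Package: pggmarkov
Title: Multi-State Markov Analysis of Repeated Public Goods Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and statistical analysis of repeated public goods
    experiments in which the synergy multiplier may change between rounds.
    Provides the game's payoff arithmetic, an agent-based generator of
    long-format contribution panels (Markov-level agents, free riders,
    full contributors, conditional cooperators, robot fill for under-sized
    groups), discretization of token contributions into five behavioural
    levels, per-round descriptive summaries, a non-homogeneous multi-state
    Markov model of level transitions with a multinomial-logistic link in
    round and treatment covariates, likelihood-ratio comparison of nested
    covariate specifications, occupancy iteration and probability flux
    toward Nash-equilibrium states, and complete-linkage clustering of
    per-player contribution trajectories with Newick export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    pracma,
    ape,
    rlang
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
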