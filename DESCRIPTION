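Package: optibias
Title: Active Inference Simulations of the Optimism Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A categorical partially observable Markov decision process
    (POMDP) engine for active inference agents -- variational state
    inference by marginal free energy descent, expected free energy
    policy selection (risk, ambiguity, novelty), and Dirichlet
    concentration-parameter learning -- together with three simulation
    experiments that study the optimism bias: loss of optimism across a
    synthetic childhood under valence and arousal exposure, asymmetric
    belief updating to good versus bad news, and engagement on a modified
    two-armed bandit task with an opt-out action.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
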