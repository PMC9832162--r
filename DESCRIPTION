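Package: epilayer
Title: Epidemic Models on Networks with Multiple Edge Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models of epidemic spread on contact networks in which edges come
    in several types ("layers"), each with its own transmissibility. Implements
    the multivariate generating-function machinery for joint excess-degree
    distributions, reproduction matrices (R-matrices) whose spectral radius
    marks the epidemic threshold, a late-stage multitype bond-percolation model
    with fixed-point escape probabilities and phase-transition scans, a
    vertex-level multilayer SIR system of ordinary differential equations with
    final-size bounds, and an exactly reduced degree-based mean-field SIR
    system. Stochastic validation oracles (configuration-model graph sampling,
    exhaustive and Monte Carlo bond percolation, event-driven Gillespie SIR)
    are included, together with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    Matrix,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
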