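Package: bpds
Title: Inference of Boolean Polynomial Dynamical Systems from Time-Series Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse engineering of gene regulatory networks as Boolean
    polynomial dynamical systems over the two-element field. Boolean update
    rules are represented as square-free polynomials over GF(2), which gives
    the model search space a vector-space structure that can be restricted,
    using an interpolation-theoretic bound, to monomials whose support does
    not exceed the base-2 logarithm of the number of observed state
    transitions. An evolutionary algorithm searches this restricted space for
    dynamic models that jointly fit wildtype and knock-out/RNAi binary time
    series, agree with prior-knowledge probability matrices, and remain
    simple. Includes discretization of continuous time courses, noise
    injection, steady-state analysis, network-comparison metrics, Latin
    hypercube parameter sampling, a synthetic fixture generator with planted
    models, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
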