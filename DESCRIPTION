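Package: rbncrit
Title: Criticality and Reservoir Performance of Random Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of random Boolean network (RBN)
    reservoirs whose Gaussian recurrent weights are controlled by the
    single parameter sigma* = sigma/mu. Provides generators for
    fixed-in-degree reservoirs, free-running and input-driven synchronous
    binary dynamics (compiled core), the analytic and empirical mapping
    from sigma* to the excitatory/inhibitory balance, BiEntropy-based
    order statistics and critical-point detection, attractor
    classification of steady-state activity, white-noise and Mackey-Glass
    task signals, and a trainable sigmoid linear readout for memory and
    prediction benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
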