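Package: motorensemble
Title: Exact Markov Analysis of Cargo Transport by Molecular Motor Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-dimensional Markov analysis of a cargo carried along a
    microtubule by an ensemble of kinesin motors. The infinite lattice model
    (occupancies of binding sites) is projected onto the finite space of
    relative motor configurations, which preserves the Markov property. The
    package enumerates relative configurations, assembles the sparse
    transition-rate generator from force-dependent single-motor kinetics
    (Michaelis-Menten stepping, processivity-based detachment, uniform
    attachment near the cargo), solves the master equation by matrix
    exponential, and computes run length, velocity, engaged-motor statistics,
    the quasi-stationary distribution conditioned on the cargo not being
    lost, and the exact step-size distribution with per-mechanism
    attribution. A Gillespie simulator of the unprojected lattice model is
    included as an independent stochastic oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
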