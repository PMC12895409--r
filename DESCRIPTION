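Package: tshrp
Title: Trajectory Surface Hopping with Pump-Generated Coherences and
    Repropagated Electronic Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed quantum-classical simulation of nonadiabatic molecular
    dynamics launched by broadband ultrashort pump pulses. Implements
    trajectory surface hopping (TSH) on analytic multi-state diabatic model
    Hamiltonians with local-diabatic electronic propagation, population-flux
    hopping, and energy-based or frozen-Gaussian decoherence corrections.
    Coherent superpositions created by a Gaussian pump (pump-generated
    coherences) can be included from the start of the coupled dynamics (full
    propagation) or added after the fact by re-integrating only the electronic
    Schroedinger equation along frozen, pulse-independent trajectories built
    from all-excited-state (AXE) or oscillator-strength-selected (SXE) nuclear
    ensembles, with the corresponding importance weights for ensemble
    expectation values split into population and coherence contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
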