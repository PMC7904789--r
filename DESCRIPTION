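Package: dwell
Title: Double-Well Attractor Models of Perceptual Evidence Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how noisy sensory
    evidence is integrated into a categorical choice. Implements the canonical
    drift-diffusion models (perfect integrator, absorbing and reflecting
    bounds) and the nonlinear double-well attractor model on a common
    Euler-Maruyama engine; psychophysical-kernel reverse correlation based on
    time-resolved ROC analysis with bootstrap errors; an analytic accuracy
    theory for the attractor model built on Kramers escape rates and a
    two-state Markov chain; double-pass choice-consistency analysis; maximum
    likelihood fitting of the attractor model to two-pulse working-memory
    accuracy data with Hessian confidence intervals and a primacy-recency
    index; a reduced-scale spiking winner-take-all network; and an n-choice
    nonlinear rate network. Includes seeded synthetic-stimulus generators for
    every experiment design the analyses consume.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    pracma,
    lhs,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
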