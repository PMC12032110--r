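Package: cqmodel
Title: Simulation and Bifurcation Analysis of the Cubic-Quadratic
    Spiking-Neuron Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a planar phenomenological
    spiking-neuron model with a cubic membrane-potential nullcline and a
    quadratic recovery nullcline.  Provides equilibrium and linear
    stability analysis via the steady-state cubic, automated detection of
    saddle-node, saddle-node-on-invariant-circle (SNIC) and Andronov-Hopf
    bifurcations and focus/node boundaries along one-parameter sweeps,
    limit-cycle diagnostics with numerical trapping-region verification,
    and a periodically forced mode with stroboscopic bifurcation diagrams,
    largest-Lyapunov-exponent estimation and interspike-interval based
    classification of quiescent, spiking, bursting and chaotic firing
    regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
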