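Package: pathmd
Title: Path-Dependent Hybrid-Hamiltonian Enhanced Sampling on Model Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic (Langevin) dynamics on built-in model potentials with an
    enhanced-sampling bias built from history-dependent action-path variables.
    The bias combines an adaptive component re-evaluated on a ladder of time
    windows with a metadynamics-style repulsive Gaussian history deposited along
    accumulated path coordinates, renormalizes both against the unbiased
    gradient, and can adaptively reweight the bias toward experimental distance
    restraints (NMR NOE or chemical-crosslink style) through the cosine overlap
    of bias and restraint vectors. Includes kinetic analyses (transition times,
    Arrhenius fits, acceleration factors), histogram free-energy landscapes,
    multi-exponential relaxation fits, dipole-fluctuation statistics, and
    restraint-fulfillment reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
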