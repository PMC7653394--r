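Package: rcpmoments
Title: Moment Dynamics and Spatio-Temporal Cumulants for Spatial
    Reactant-Catalyst-Product Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous-space stochastic agent-based models of the
    reactant-catalyst-product (RCP) class: an exact event-driven (Gillespie)
    simulator on a periodic torus with truncated interaction kernels and
    persistent agent identities; perturbation-expansion moment equations
    (mean-field densities, Fourier-space second-order spatial cumulants, and
    the first-order density correction); the auxiliary original/past/new-agent
    construction that turns spatio-temporal correlations into spatial
    correlations of an expanded model; a direct linear equation for the
    spatio-temporal cumulant; and binned estimators of densities, spatial and
    spatio-temporal cumulants from simulated point configurations.  Includes
    closed forms for the spatial and stochastic logistic model and a
    host-parasite model factory, and end-to-end comparison of analytical
    predictions with simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
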