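Package: rotaratchet
Title: Simulation and Irreversibility Analysis of AC-Driven Rotary Brownian Ratchet Motors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying nanoscale rotary motors that operate as Brownian
    ratchets in a switching energy landscape. Provides an overdamped Langevin
    simulator of a rotor arm in a periodic intrinsic potential modulated by a
    square-wave AC electric field (with axis, frequency and amplitude sweep
    protocols and a torsional-spring motor variant), a generator of synthetic
    TIRF-style tracked tip-position tables, trajectory statistics (cumulative
    angular displacement, angular velocities, speed histograms, speed versus
    field axis, turns per field cycle, dwell-position detection), a
    stochastic-thermodynamics irreversibility analysis (kernel-density
    transition estimates, entropy production versus displacement, slope
    renormalization and collapse, effective drift and diffusion coefficients,
    mean-squared-displacement crossover), and analytic motor-mechanics
    calculators (rotational friction, torque, dissipated power, loaded
    operation and the nominal efficiency bound).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
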