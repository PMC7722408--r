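Package: bgresonance
Title: Delay-Induced Beta Oscillations in a Cortex-Basal-Ganglia Loop Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the reduced cortex-subthalamic nucleus-globus pallidus
    ("resonance") firing-rate model with a common synaptic transmission delay.
    Computes equilibria, the delayed linearization and its transcendental
    characteristic equation, all imaginary-axis crossings and critical delays,
    the transversality derivative, zero-delay Routh-Hurwitz stability, and the
    Hopf normal-form coefficients (first Lyapunov-type coefficient, bifurcation
    direction, orbital stability and period trend) via center-manifold
    reduction. Includes an Euler integrator for the delay system with ramped
    one- and two-parameter bifurcation scans, oscillation-band classification
    (alpha/beta/gamma), and seeded fixture generation for admissible parameter
    sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
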