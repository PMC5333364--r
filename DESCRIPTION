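Package: mucadrop
Title: Shape-Free Free-Energy Barriers of Droplet and Polymer Cluster
    Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multicanonical flat-histogram Monte Carlo simulation of the
    condensation-evaporation transition in a dilute Lennard-Jones gas and
    a dilute bead-spring (FENE) polymer solution at fixed density.
    Estimates the conformational density of states from flat-histogram
    sampling, converts it to the total-energy ensemble by explicit
    kinetic-energy convolution, extracts finite-size transition
    temperatures and free-energy barriers by the equal-height and
    equal-area constructions, propagates errors by jackknife resampling,
    and fits finite-size scaling laws for barrier and transition
    temperature.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
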