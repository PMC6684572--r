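Package: rootbend
Title: Mass-Spring Simulation of Lateral-Root Gravitropic Bending and
    Set-Point Angle Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-dimensional cell-grid mass-spring model of an emerged
    lateral root in which turgor pressure and asymmetric anisotropic growth
    of wall springs drive gravitropic bending, together with the statistics
    layer used for gravitropic set-point angle (GSA) phenotyping: angle
    category binning with per-plate percentages and across-plate SEM, a
    two-sample Kolmogorov-Smirnov comparison of angle distributions, and a
    synthetic generator of plate-structured GSA datasets. Scenario runs
    alternate damped Newtonian relaxation of the spring lattice with
    resting-length growth steps and record the time evolution of the organ
    bending angle and flank cell sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
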