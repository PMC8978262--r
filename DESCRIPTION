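Package: tetramc
Title: Tetrahedral-Mesh Monte Carlo Photon Transport and Photodynamic
    Therapy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulation of light propagation in three-dimensional
    tissue volumes represented as tetrahedral meshes, with the dosimetry and
    planning layer needed for interstitial photodynamic therapy (iPDT):
    photon-packet transport with Henyey-Greenstein scattering and Fresnel
    interface physics, six light-source models (point, pencil beam, cut-end
    cone fiber, cylindrical diffuser, ball and volume emitters, surface
    emitters), per-element fluence-rate estimation with absorption and
    track-length estimators, dose-volume histograms and threshold-model
    necrosis, coverage-constrained source power optimization with optional
    simulated-annealing source repositioning, optical-property lookup-table
    generation and inversion, and a diffuser dose-escalation workflow under a
    vessel-wall fluence-rate cap. Meshes are read and written as legacy VTK
    unstructured grids; synthetic phantom generators provide test geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    boot,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
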