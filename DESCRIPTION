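Package: tactrivalry
Title: Hierarchical Neural Competition Model of Tactile Perceptual Rivalry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of perceptual bistability evoked by
    antiphase vibrotactile pulse trains delivered to the two hands. Implements
    a hierarchical two-stage firing-rate competition model: a first stage of
    adapting recurrent units that alternate between UP and DOWN states under
    Ornstein-Uhlenbeck noise, and a second stage of mutually coupled units
    with fast excitation and delayed, slowly decaying inhibition that encode
    the simultaneous (SIM) and apparent-movement (AM) percepts. Provides
    Euler-Maruyama integration of the full and simplified models, percept
    classification and dominance-duration extraction, duration statistics
    (coefficient of variation, skewness ratio, Kolmogorov-Smirnov fits of
    gamma and log-normal distributions, lag correlations), stimulus-parameter
    sweeps (Levelt's proposition II, simulation-based bistability mapping),
    and least-squares/evolutionary fitting of the input nonlinearity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    lhs,
    fitdistrplus,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
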