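Package: atne
Title: Eco-Evolutionary Allometric Trophic Network Simulation with Evolving Fish Growth Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a pelagic food web as an allometric trophic network in which two
    focal fish species carry evolving von Bertalanffy growth traits (asymptotic length
    and Brody's growth coefficient) on a discrete genotype grid, subjected to
    size-selective fishing. Provides the seasonal food-web ODE core, a multivariate
    normal inheritance kernel over the trait grid with heritability tracking, Bayesian
    lognormal fitting of the von Bertalanffy growth model to length-at-age data,
    bell-shaped gear-selectivity fitting to catch-by-length-class data, synthetic data
    generators for all inputs, and a driver for burn-in/fishing scenarios and
    sensitivity grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
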