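Package: avianITV
Title: Hierarchical Bayesian Analysis of Within-Population Phenotypic
    Variation in Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates within-population phenotypic variation
    (coefficients of variation of body mass and wing length) for
    location-by-species groups of banded birds with a hierarchical
    Bayesian model, propagates the full posterior uncertainty into a
    measurement-error regression of CV on geographic and environmental
    covariates with correlated species-specific coefficients, and into an
    among-species regression on life-history covariates with
    phylogenetically correlated intercepts.  Includes the data-cleaning
    rules of the source analysis (adult males, first capture per season,
    MAD outlier exclusion, minimum sample-size and latitude-span
    criteria), construction of spatial and temporal environmental
    variability covariates from a productivity raster, distance to range
    edge with small-gap closing, MCMC convergence diagnostics, and a
    synthetic-data generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    ape,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
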