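Package: aflpselect
Title: Climate-Dependent Selection Scans for Dominant Marker Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of climate-dependent differential selection on
    quantitative traits from dominant (0/1) marker data such as AFLP
    fingerprints. Implements Bayesian allele-frequency estimation for
    dominant loci, locus-wise F_ST with a neutral simulation envelope and
    trimmed-mean baseline, a hierarchical Bayesian F-model outlier scan,
    univariate logistic environment-allele association scans with G and
    Wald tests, AMOVA-based Phi_PT differentiation, Mantel
    isolation-by-distance tests, multivariate distance-matrix regression
    (GAMOVA) of trait means on genetic differentiation, and a scenario
    classifier that combines these tests to separate clinal selection,
    local selection, neutral geography and chance. A geometric
    morphometrics toolkit (elliptic Fourier outline analysis, generalized
    Procrustes alignment, shape PCA) derives shape traits from leaf
    outlines and flower landmark configurations, and a synthetic-data
    generator produces complete marker/climate/trait/shape bundles with
    known ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vegan,
    geosphere,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
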