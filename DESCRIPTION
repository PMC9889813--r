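Package: natalclust
Title: Spatial Cluster Detection for Low Birth Weight and Preterm Birth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Municipality-level spatial analysis of adverse birth outcomes
    (low birth weight and preterm birth): cohort classification and
    exclusions, direct and indirect maternal-age standardization of
    incidence, spatially structured (local) empirical Bayes smoothing of
    age-standardized rates toward the neighborhood mean, Tango's general
    clustering test, and a circular Poisson spatial scan statistic with
    Monte Carlo inference reporting the most, second and third likely
    clusters. Includes a synthetic birth-registry generator (heavy-tailed
    municipality denominators, age-structured baseline rates, planted
    circular risk clusters) so every stage can be exercised and calibrated
    without access to restricted vital-registration microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
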