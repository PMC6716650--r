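Package: arealscan
Title: Circular and Flexible Spatial Scan Statistics for Areal Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and comparison of spatial clusters in areal
    (county-level) count data under the discrete Poisson model. Implements
    Kulldorff-style circular scan statistics with a population-fraction
    window cap, Tango-Takahashi-style flexible (irregularly shaped) scan
    statistics with the restricted log-likelihood ratio, Monte Carlo
    inference conditional on the total case count, two-step covariate
    adjustment via Poisson offset regression, and a formal comparison
    toolkit for two cluster solutions: membership contingency, exact
    McNemar test, Cohen's kappa and prevalence-and-bias-adjusted kappa
    with confidence intervals, two-sample proportion tests, and the
    Cluster Information Criterion. Includes a synthetic areal-data
    generator for lattices with embedded high-risk zones, Jenks natural
    breaks classification, and GeoJSON import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
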