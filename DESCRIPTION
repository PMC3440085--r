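Package: qhtscall
Title: Three-Stage Activity Calls for qHTS Concentration-Response Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies quantitative high-throughput-screening (qHTS)
    concentration-response profiles into toxicologically relevant activity
    categories via a three-stage decision tree: robust Hill-model
    concentration-response (both unweighted and neighbor-weighted nonlinear
    least squares beat a flat line), potent response beyond the assay
    detection limit at the lowest tested concentration (weighted t-test),
    and non-robust but statistically significant profiles. Includes a
    simulator for labeled screening data sets under constant or
    concentration-dependent residual error, and an evaluation harness
    computing type I error, power, ROC curves and trapezoid AUC, plus
    single-stage comparator methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
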