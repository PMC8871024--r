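Package: ovaresp
Title: Ovarian Response Prediction and Perturbation-Based Feature Importance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression modelling of the ovarian response to controlled ovarian
    stimulation in IVF cycles. Generates calibrated synthetic clinical cohorts,
    screens candidate impact features by univariate Pearson correlation, trains
    a Levenberg-Marquardt feed-forward neural network and an epsilon-insensitive
    Gaussian-kernel support vector regressor of the number of oocytes retrieved,
    evaluates them (RMSE, regression coefficient R, error fractions), and ranks
    features by the normalized mean impact value, a perturbation-based
    importance statistic. Includes an iterative gonadotropin dose-tailoring
    loop and ovarian-response risk flags for clinical decision support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
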