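Package: cpmrisk
Title: Connectome-Based Predictive Modeling of Substance-Use Vulnerability Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage pipeline for modeling behavioral vulnerability to
    substance use in children. Stage one normalizes heavily right-skewed
    questionnaire items with the Yeo-Johnson power transform, extracts latent
    dimensions by principal components analysis with Bayesian (Laplace
    evidence) dimensionality selection, and assesses loading reliability by
    bootstrap. Stage two predicts those dimensions from functional-connectivity
    edges with ridge regression under nested 10-fold cross-validation
    (leakage-safe train-set standardization, inner alpha tuning), evaluating
    performance as the partial correlation between predicted and observed
    scores adjusted for head motion and data quantity, with percentile
    bootstrap confidence intervals. Includes connectome construction from
    parcellated time series (confound regression, temporal smoothing,
    Fisher-z Pearson connectivity, motion QC), model characterization by
    functional network, and a synthetic-data generator with known ground
    truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), car, jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
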