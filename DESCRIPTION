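Package: bpc
Title: Calibrated Disorder Probabilities from Polygenic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts an individual's polygenic score into a calibrated
    absolute disorder probability using only GWAS summary statistics, a
    population reference panel, a prior disorder probability, and the
    disorder's lifetime prevalence (the Bayesian polygenic score
    Probability Conversion, BPC). Implements the liability threshold
    mathematics (scale conversions, truncated-normal case/control score
    moments, Lee et al. R2 conversion), linkage-equilibrium posterior-mean
    effect-size shrinkage, a liability-threshold case/control simulator
    with efficient ascertained sampling, comparator conversion methods
    (quantile-based, linear rescaling, tuned variants), and calibration
    metrics (Integrated Calibration Index, calibration slope/intercept,
    AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
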