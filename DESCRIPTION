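Package: tremorlab
Title: Accelerometry-Based Differentiation of Essential Tremor and Parkinsonian Tremor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for differentiating essential tremor (ET)
    from Parkinson's disease (PD) tremor in hand accelerometer recordings.
    Implements canonical signal preparation (vector amplitude sum, resampling
    to 100 Hz, 15 s segmentation, 2-30 Hz band-pass, z-normalisation,
    more-affected-hand selection), the six standard tremor characteristics
    (band power AUC, tremor stability index, half-width power, peak frequency,
    FWHM, peak power), two time-series model features that separate the
    diseases (the Kolmogorov-Smirnov statistic of standardised AR-GARCH(1,1)
    residuals against a normal distribution, and the best train log-likelihood
    of Gaussian hidden Markov models with 2-4 states), patient-grouped
    cross-validated classification with exhaustive feature-combination search
    and segment-length ablation, and a phenotype-conditioned synthetic tremor
    cohort generator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    randomForest,
    data.table,
    jsonlite,
    yaml,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
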