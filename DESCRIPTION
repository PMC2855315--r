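Package: hedonose
Title: Predicting Odor Pleasantness from Electronic-Nose Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for tuning an electronic nose (eNose) to
    the primary perceptual axis of human olfaction, odor pleasantness.
    Raw multi-sensor odorant measurements (8 metal-oxide plus 8 quartz
    microbalance sensor time series) are reduced to a 120-feature kinetic
    signature, screened by a nearest-centroid clustering quality control,
    normalized to remove sensor-type and vapor-concentration bias, and
    mapped to median human pleasantness ratings by an ensemble of small
    feed-forward neural networks trained by batch gradient descent.
    Includes the full evaluation battery (leave-group-out cross-validation,
    hedonic sign classification with mid-scale exclusion bands, permutation
    null calibration, power analysis, and human inter-rater agreement
    statistics) and a synthetic-data module that emulates both the sensor
    physics and the human raters so that every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, nnet
Config/testthat/edition: 3
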