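Package: reidrisk
Title: Reidentification Risk Assessment for Clinical Speech Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates adversarial speaker-reidentification (marketer) attacks on
    de-identified speech data sets at the embedding level. Provides a Gaussian
    speaker-embedding cohort generator with task-dependent cross-task mismatch, a
    two-covariance probabilistic linear discriminant analysis (PLDA) verifier with
    exact log-likelihood-ratio scoring, detection-cost-function (minDCF) and
    equal-error-rate threshold calibration with bootstrap averaging over speaker
    subsets, known/unknown speaker-split sampling with probe withholding, attack
    execution with acceptance variants, and risk statistics (true/false acceptances,
    precision, false-acceptance rate, FA/TA ratios, correlation of false acceptances
    with search-space size).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
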