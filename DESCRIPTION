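Package: adirsig
Title: Behavioral Signature Classification of ADI-R Symptom Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised classification of genetic-disorder membership from the
    37 ordinal items of the Autism Diagnostic Interview-Revised (ADI-R)
    diagnostic algorithm. Implements nested leave-one-out cross-validation of a
    one-vs-one radial-basis-function support vector machine ensemble with Platt
    sigmoid calibration and pairwise probability coupling, application of the
    trained classifier to blind (idiopathic) cohorts with item-permutation and
    label-permutation nulls, sibling-pair familiality statistics (concordance
    chi-square, probability and principal-component correlations, variance
    tests, severity-versus-specificity regressions), unsupervised screens
    (principal component analysis with out-of-sample projection, k-means
    quality metrics), and a calibrated synthetic-cohort generator based on a
    latent-severity ordered-threshold item model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
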