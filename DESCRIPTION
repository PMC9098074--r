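Package: specwait
Title: Specialty Labelling of Referral Notes and Wait-Time Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gold-standard target-specialty labels for primary-care
    referral notes from their co-occurrence with administrative consult
    claims, trains and selects one-vs-rest regularized logistic-regression
    text classifiers under precision-floor, recall-floor and best-F1
    schemes, and uses the gated classifiers to estimate per-specialty
    referral-to-consult wait-time percentiles with bootstrap confidence
    intervals. Includes a synthetic EMR+claims cohort generator so the
    whole pipeline can be exercised and validated without access to
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
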