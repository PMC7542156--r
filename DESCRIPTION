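Package: sibmlr
Title: Multilevel Classification of Self-Injurious Behavior from Wrist Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A group-level analysis pipeline for detecting self-injurious
    behavior (SIB) in autism spectrum disorder from tri-axial wrist
    accelerometer recordings. Sessions are low-pass filtered and segmented
    into overlapping two-second windows; each window yields 96 features (57
    time-domain, 12 frequency-domain, and 27 nonlinear motor-variability
    measures: sample entropy, cross-sample entropy, recurrence
    quantification, and detrended fluctuation analysis). Features are
    reduced by lasso selection followed by principal component analysis and
    classified with a multilevel logistic regression carrying
    participant-level random intercepts and slopes, alongside a bank of
    comparison classifiers. A synthetic cohort generator with controllable
    episode structure and participant heterogeneity supports end-to-end
    testing without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    lme4,
    e1071,
    rpart,
    class,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
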