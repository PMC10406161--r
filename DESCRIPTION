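Package: transtime
Title: Cross-Species Age Translation from Developmental Event Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to align ages across the lifespan of primate species.
    Builds a common 0-1 event scale from multi-species tables of
    developmental, behavioural and transcriptional time points (with
    iterative imputation of unobserved species-by-event cells), fits the
    translating-time regression of log age on the event scale, species,
    event type, their interactions and a quadratic scale term, and inverts
    the fit to translate an age in one species into its equivalent in
    another.  Additional time points are minted from transcriptomic age
    transfer (training age predictors on one species' expression and
    applying them to another), from milestones of nonlinear growth fits,
    and from attainment ages of monotone count series.  Includes
    within-species variation summaries (coefficient of variation across
    populations, sex-slope regressions), rescaling of survival curves onto
    a reference species' timeline, and seeded synthetic-data generators
    with known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    withr,
    Matrix,
    glmnet,
    e1071,
    randomForest,
    kernlab,
    caret,
    minpack.lm,
    flexsurv
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
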