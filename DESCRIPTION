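Package: pupilscreen
Title: Pupillometric Feature Engineering and Nested Cross-Validated
    Screening for ADHD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for task-evoked pupillometry as an objective
    screening biomarker for attention-deficit/hyperactivity disorder (ADHD).
    Provides trial-level preprocessing (cubic-spline imputation of blink
    gaps, missingness-based trial exclusion, moving-average reduction),
    a catalogue of 22 custom dilation-velocity/acceleration features plus
    general time-series features (absolute energy, real Fourier
    coefficients, change-quantile variance, approximate entropy, peak
    counts, linear-trend standard error), Mann-Whitney U and one-way
    ANOVA-F univariate feature ranking, leakage-safe repeated nested
    ten-fold cross-validation of binary classifiers with per-fold
    univariate selection, RadViz class-separability projection, and a
    seeded synthetic cohort generator emulating a 50-subject stimulus-
    locked pupillometry study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    rpart,
    randomForest,
    glmnet,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
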