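Package: cuffbp
Title: Cuffless Blood Pressure Estimation from ECG and PPG Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking cuffless blood-pressure estimation from
    electrocardiogram (ECG) and photoplethysmogram (PPG) waveforms. Implements
    a closed-form hemodynamic model linking pulse transit time, pulse intensity
    ratio and the Womersley number to pulse pressure and diastolic pressure; a
    seeded synthetic generator for ECG/PPG/arterial-pressure records and
    feature tables with that generative structure; fiducial detection and
    extraction of pulse arrival time, pulse rate and eight pulse-wave
    morphology features averaged over five clean cardiac cycles; five
    regression families (elastic net, boosted regression trees, support vector
    regression, a feed-forward neural network and a single-step LSTM cell)
    with a fixed hyperparameter grid and a lowest-error-SD selection rule;
    leave-one-out and holdout evaluation protocols with bias/SD/confidence
    interval summaries, IEC 80601-2-30 criterion-1 grading and Bland-Altman
    agreement; and two-way ANOVA, Levene tests and Holm-corrected post hoc
    comparisons across methods and feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    glmnet,
    xgboost,
    e1071,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
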