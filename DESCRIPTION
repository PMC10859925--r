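Package: statedetect
Title: Unsupervised Detection of Functional States in Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects time-continuous functional states in multichannel
    physiological recordings with an ensemble change-point method built on
    connectivity-constrained Ward agglomeration (the State-Detecting
    Algorithm). Ships the full feature-engineering recipe it expects
    (adaptive multitaper band power, power ratios, sliding-window coherence
    and phase-locking indices over spatial regions of interest), the
    log/z-score/PCA reduction, and a ground-truth-free validation suite:
    state-adapted cluster-validity indices, weight-of-evidence information
    values, nonparametric paired statistics with Bonferroni correction, and
    predictive-model checks. Includes a seedable generator of
    piecewise-stationary synthetic recordings with planted states,
    epoch-shuffled surrogates, and state-rearranged variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pROC,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
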