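Package: vrtsleep
Title: Verbal Reaction Time Extraction and Voice-Based Sleepiness Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking verbal reaction time (VRT), extracted
    from cognitive-test audio recordings by amplitude-threshold speech onset
    detection, to ecological momentary assessment (EMA) sleepiness ratings in
    older adults. Provides a synthetic cohort and audio generator for fully
    reproducible testing, speech/non-speech validation arithmetic with
    predictive-value metrics and a flow-accounting ledger, dataset assembly
    with an exclusion cascade, an association cascade (random-forest
    importance screening, linear regression, RESET misspecification test,
    generalized additive model, AIC/ANOVA comparison), and a patient-level
    stratified cross-validated random-forest classifier of sleepiness levels
    with class balancing and bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lmtest,
    mgcv,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
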