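Package: aclimage
Title: Auditory Classification Images for Phoneme Categorization in Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates phoneme-categorization-in-noise experiments (formant-
    synthesized /aCCa/ nonword targets, trial-unique Gaussian noise, a
    3-down 1-up adaptive staircase, linear template observers) and estimates
    each listener's Auditory Classification Image (ACI) by smoothness-
    penalized logistic regression on noise cochleograms with 10-fold
    cross-validated selection of the smoothing level. Includes the group and
    individual analyses used with ACIs: cluster-based permutation tests on
    time-frequency weight maps, region-of-interest comparisons, auto- and
    cross-prediction deviances with a per-listener strategy-specificity
    index, and a two-step individual deviance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
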