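Package: gaitsubpop
Title: Biomechanical Subpopulation Discovery and Surgical-Response
    Analysis for Gait Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for discovering biomechanical subpopulations of
    hip-osteoarthritis patients from time-normalized gait waveforms and
    for quantifying subpopulation-specific surgical response. Provides a
    synthetic gait-waveform cohort generator, healthy-control-referenced
    standardization with cross-cohort principal-component projection,
    consensus k-means subpopulation discovery guided by Ward hierarchical
    clustering, linear support-vector-machine classification with
    closed-form Shapley back-projection to per-waveform importance, a
    classifier-oriented gait score (COGS) defined as the signed orthogonal
    distance to the SVM hyperplane, and one-dimensional waveform
    inference with family-wise error control by max-statistic
    permutation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    cluster,
    e1071,
    ggplot2,
    grDevices,
    jsonlite,
    pROC,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
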