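Package: neuropda
Title: Simulation and Analysis of Mindfulness-Based Real-Time fMRI
    Neurofeedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation and analysis toolkit for closed-loop
    real-time fMRI neurofeedback targeting the default mode network (DMN)
    and frontoparietal network (FPN). Provides a synthetic BOLD phantom
    generator with known ground truth, a personalized network localizer
    (spatial ICA with template matching and top-voxel thresholding), an
    incremental per-voxel general linear model engine (Gentleman's
    algorithm) emitting Positive Diametric Activity (PDA) z-scores, an
    adaptive feedback controller with within- and between-run calibration,
    post-hoc mPFC-PCC connectivity cleaning and mixed-effects analyses,
    repeated-measures ANOVA power via the noncentral F distribution, and
    stratified randomization.
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
    rlang,
    generics,
    ggplot2,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
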