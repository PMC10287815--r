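Package: pelvimech
Title: Biaxial Vaginal Wall Biomechanics and Urethral Electrophysiology
    Pipelines for Simulated Childbirth Injury Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for rodent simulated-childbirth-injury
    studies combining planar biaxial tensile testing of the vaginal wall with
    urethral and pudendal-nerve electrophysiology. Implements cyclic-loading
    segmentation, steady-cycle selection, slope-based stiffness, tangent modulus
    over the terminal strain window, and the anisotropy index
    (longitudinal/transverse tangent modulus); leak point pressure extraction and
    EMG/ENG firing-rate and amplitude deltas; and the group-level statistical
    layer (Kruskal-Wallis with Dunn post hoc tests, two-way repeated-measures
    ANOVA and mixed models with Bonferroni-adjusted contrasts, and t-test based
    sample-size calculation). A synthetic cohort generator with fully known
    ground truth (exponential toe-region material with hysteresis and
    preconditioning, Poisson spike trains, pressure ramps to a leak point)
    supports validation and power simulation when raw study data are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
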