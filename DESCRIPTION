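Package: tempobias
Title: Analysis of Pitch-Induced Biases in Perceived Tempo
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for relative tempo judgment experiments in
    which listeners rate repeating tones against a metronomic standard.
    Covers constrained stimulus and trial design (log-spaced interonset
    interval grids, equal-temperament pitch ladders, loudness-balanced
    block randomization, additive tone synthesis and WAV export),
    participant screening, per-subject response-scale calibration with
    Cook's-distance outlier exclusion, the illusory tempo shift statistic
    in log2-percent units, orthogonal polynomial curve characterization,
    and the group-level multivariate layer (Hotelling's T-squared tests,
    repeated-measures MANOVA with Wilks' lambda, repeated-measures ANOVA
    with sphericity corrections, Holm-Bonferroni post hocs, Cohen's d and
    partial eta-squared). Includes a synthetic rater generator for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
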