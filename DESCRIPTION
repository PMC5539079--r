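Package: endowm
Title: Endothelial Function and White-Matter Health Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking peripheral endothelial
    function to white-matter health. Quantifies white-matter hyperintensity
    volume on FLAIR-like volumes by two-Gaussian intensity-histogram modelling
    with a 2.33-SD dominant-component threshold, computes the reactive
    hyperemia index from fingertip pulse-amplitude recordings as the
    post- to pre-occlusion average signal-size ratio, hard-segments a
    white-matter seed cluster by strongest streamline connectivity with
    target-size normalization, runs covariate-adjusted voxelwise association
    of fractional anisotropy with max-statistic permutation family-wise
    error control, and provides the cohort-level correlation and
    group-difference statistics. Ships seeded synthetic-data generators
    (intensity phantoms, pulse signals, connectivity counts, cohort tables)
    so every stage is testable end to end without private imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
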