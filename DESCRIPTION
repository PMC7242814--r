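Package: dediffr
Title: Neural Dedifferentiation Analysis for Category-Selective fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying age-related neural dedifferentiation in
    category-selective cortex with a face/scene associative-encoding,
    subsequent-memory design. Provides a synthetic cohort generator (study/test
    list structure, behavioral outcomes, trial-wise voxel patterns, and BOLD
    time series), least-squares-all single-trial GLM estimation, contrast-based
    ROI definition, the univariate differentiation index and its
    attenuation/broadening decomposition, cross-session within- minus
    between-category multivoxel pattern similarity, single high-threshold
    source-memory scoring, and the accompanying inferential layer (Welch t
    tests, Cohen's d, mixed-design ANOVA with Greenhouse-Geisser correction and
    partial eta squared, partial correlations, interaction-screened
    regressions, and factor-score projection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
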