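Package: sleepfc
Title: Permutation Statistics for Resting-State Network Functional
    Connectivity Across Sleep Stages
Version: 0.1.0
Authors@R: person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Edge-level analysis of inter-network functional connectivity
    (FC) across wakefulness, NREM2, slow-wave and REM sleep: polynomial
    trajectory classification of stage-coded FC edges with
    permutation-tested R-squared and Holm-Bonferroni correction,
    angular-distance permutational MANOVA between stage FC vectors with
    post-hoc pairwise tests, directional classification of wake-to-NREM FC
    transitions (reduction, increase, reversal) with binomial composition
    tests, Fisher r-to-z edge FC with autocorrelation-aware effective
    degrees of freedom, and a synthetic multi-state connectome generator
    with planted trajectory archetypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
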