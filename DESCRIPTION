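Package: gradflex
Title: Task Modulation of Cortical Connectivity Gradients from Informational Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the principal connectivity gradient of the
    cortex is flexed by semantic task demands. Builds parcel-by-parcel
    informational connectivity from trial-level multivoxel activation
    patterns, decomposes it into cortical gradients (row sparsification,
    cosine affinity, PCA), estimates the dimensionality of local neural
    representations by searchlight PCA across participants, aligns
    inter-participant semantic rating similarity with neural pattern
    similarity (second-order representational similarity analysis), and ties
    the three together with bootstrap mediation. Includes spin permutation
    tests for spatially autocorrelated parcel maps, exact and approximate
    rank tests, repeated-measures ANOVA with Greenhouse-Geisser correction,
    and a synthetic-data generator with planted ground truth (latent
    gradient, condition-dependent modulation, latent rank, rating-brain
    coupling) so that every stage of the pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
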