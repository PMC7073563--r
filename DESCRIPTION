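Package: lvscape
Title: Latent-Variable Landscape Analysis of Nerve Sheath Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects bulk tumor expression into a transferred PLIER-style
    latent-variable space and characterizes the latent variables that
    distinguish NF1 nerve sheath tumor types. Provides ridge-regularized
    projection onto a non-negative loading matrix, correlation-based
    deduplication of latent variables, an ensemble-of-random-forests
    feature-selection procedure with resampled importance distributions and
    Mood's median test, marker-based and constrained-least-squares immune
    deconvolution, rank-based regulon activity inference with multi-network
    consensus, hierarchical clustering of latent variables by protein-activity
    profiles with preranked drug-target set enrichment, gene-variant versus
    latent-variable association tests, and a synthetic-data generator with
    recorded ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
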