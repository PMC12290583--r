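Package: metaclique
Title: Coordinate-Based Meta-Analysis and Connectivity-Profile Cliques
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Activation likelihood estimation (ALE) coordinate-based
    meta-analysis with Monte-Carlo family-wise error inference, conjunction and
    permutation subtraction contrasts, seed-ROI extraction from meta-analytic
    peaks, meta-analytic coactivation modeling against a term-annotated
    coordinate database, desk-scale seed-based resting-state functional
    connectivity, multimodal connectivity-profile correlation matrices, Ward
    hierarchical clustering of regions into cliques, and term-based functional
    decoding. Ships a synthetic-data generator with planted ground truth so the
    whole pipeline is exercisable and testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ape,
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
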