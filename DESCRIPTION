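Package: endostruct
Title: Structural Interactome Assembly for Purified Organelles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds an organelle-centered structural protein interactome from
    cross-linking mass spectrometry (XL-MS) and blue-native co-fractionation
    (BN-MS) evidence. Scores candidate organelle-resident proteins by combining
    multi-study presence, organelle-IP abundance and reference-interaction
    metrics with a partial-AUC/false-positive-rate calling procedure; filters
    co-elution and cross-link tables with replicate-consensus and score rules;
    integrates the evidence into an endosome-centered network with
    edge-betweenness communities, degree-preserving rewiring nulls and 3-clique
    enumeration; validates structural models of protein pairs and trios against
    Calpha-Calpha cross-link distance constraints with per-residue confidence
    gating; and scans disease variants against predicted interfaces. A
    synthetic-data module generates every input with known ground truth so the
    whole pipeline runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
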