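Package: scmpep
Title: Scoring Card Method for Peptide Bioactivity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretable classification of short bioactive peptides with the
    scoring card method (SCM), applied to tumor-homing peptides. Estimates
    per-residue propensity scores from class compositions, refines them with a
    genetic algorithm whose fitness combines cross-validated AUC with fidelity
    to the initial scores, classifies peptides by a composition-weighted sum
    against a threshold, and characterizes learned score cards by correlation
    with AAIndex physicochemical property scales. Includes peptide property
    calculators (molecular weight, net charge, 280 nm extinction coefficient),
    a synthetic peptide generator with controllable residue enrichment, ROC and
    confusion-matrix metrics, broom-style tidiers, and ggplot2 visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
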