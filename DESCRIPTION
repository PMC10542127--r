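Package: icimyo
Title: Single-Cell and TCR Repertoire Analytics for Checkpoint-Inhibitor
    Myocarditis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for multi-compartment (heart, blood,
    tumor) single-cell and T-cell-receptor repertoire studies of
    immune-checkpoint-inhibitor myocarditis: mixed-effects logistic
    differential abundance with likelihood-ratio tests, AUROC and
    moderated-t marker discovery, pseudobulk negative-binomial Wald
    differential expression, TCR-beta clonal expansion and
    control-tissue-normalized enrichment, Hill diversity profiles,
    heart-blood clonotype sharing tests, permutation-based
    receptor-ligand interaction scoring, and serum analyte statistics.
    Includes a fully parameterized synthetic-cohort generator so every
    stage is testable end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    limma,
    vegan,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
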