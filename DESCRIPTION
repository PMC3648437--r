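Package: seroscreen
Title: Autoantibody Discovery from Protein Microarray Serology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for serum IgG autoantibody discovery on
    high-density protein microarrays: GenePix-style spot-level import,
    robust linear-model normalization of per-array scale effects on
    control spots, exact permutation M-statistics with
    Chebyshev/Cantelli bounds and fold-change filtering for
    case/control differential reactivity, cytogenetic-locus and
    differential-expression-ratio candidate prioritization, and
    ELISA-panel logistic classifier evaluation with full diagnostic
    metrics. Includes seeded synthetic-data generators with known
    ground truth so every stage is testable without raw scans or sera.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
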