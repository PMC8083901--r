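Package: slmarker
Title: Synthetic-Lethality-Guided Prognostic Marker Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens candidate synthetic-lethal gene pairs against tumor/control
    expression data (quantile normalization, log ratios versus averaged controls,
    fold-change regulation calls, co-expression pattern fractions, a label-permutation
    null and Storey q-value FDR), encodes an immunohistochemistry stain panel with
    ordinal-grade cutoff rules and per-patient over/under calls, enumerates single and
    paired protein markers, and runs a constrained survival screen (Kaplan-Meier,
    log-rank, univariate and stage-adjusted Cox proportional-hazards models, stepwise
    AIC covariate entry, and two-marker combinations). Ships synthetic-data generators
    with known ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    MASS
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
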