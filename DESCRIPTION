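Package: exoNED
Title: Extracellular-Vesicle Small-RNA Markers of Neuroendocrine
    Differentiation in Castration-Resistant Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting therapy-induced neuroendocrine
    differentiation from serum extracellular-vesicle (EV) small-RNA
    profiles. Implements isomiR calling against a mature-miRNA reference
    with seed-integrity checks, negative-binomial differential expression
    with median-of-ratios normalization, construction of EV-miRNA
    classifiers by leave-pair-out cross-validation with nested Boruta
    feature selection over random forests, EV-versus-tissue concordance
    calling, comparative-Ct quantification, and four-parameter-logistic
    ELISA standard-curve diagnostics with threshold classification.
    Includes a synthetic-cohort generator emulating the statistical
    structure of EV small-RNA sequencing so every stage is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    ranger,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
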