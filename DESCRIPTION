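Package: recurSig
Title: Prognostic Gene-Signature Discovery and Validation for Colorectal
    Liver Metastases
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for discovering and validating gene-expression
    signatures that predict disease-free survival after resection of
    colorectal liver metastases. Implements risk stratification by
    recurrence time, gene ranking by signal-to-noise ratio, Welch t
    statistic and univariate Cox Wald statistics, a multiple-sampling
    (repeated 2/3 resampling) discovery procedure with rank averaging
    and pooled cross-validated AUC, nearest-mean (centroid)
    classification with leave-one-out forward selection, Kaplan-Meier /
    log-rank / Cox survival validation, five configurable clinical risk
    scores, permutation-ANOVA differential expression for treatment
    effects, print-tip loess normalization and dye-swap merging for
    two-channel microarrays, and a synthetic-cohort generator that
    emulates the joint structure of clinical covariates, censored
    survival and expression used to test every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    SummarizedExperiment,
    S4Vectors,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, Microarray, Survival, Classification
RoxygenNote: 7.3.3
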