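Package: metasig
Title: Immune Gene-Signature Discovery and Validation for Metastasis
    Prediction in Early Colorectal Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and validating prognostic gene-expression
    signatures in small, imbalanced tumour cohorts. Implements bootstrap
    recursive-SVM multivariate feature selection with out-of-bag error
    ladders, generalized-log variance stabilization, a Welch-t differential
    expression screen with Benjamini-Hochberg control, unconditional
    hypergeometric gene-set over-representation (including a utility that
    reconstructs unprinted selection and universe sizes from a published
    enrichment table), a below-median count classifier with ROC cutoff
    selection, Kaplan-Meier / Mantel-Cox survival stratification, and
    delta-delta-Ct qPCR relative quantification with exact Mann-Whitney
    comparison. A synthetic cohort generator with planted, heterogeneously
    down-regulated signature genes makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
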