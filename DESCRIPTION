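Package: medewas
Title: Epigenome-Wide Mediation Analysis of Psychosocial Stress and
    Cardiometabolic Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for high-dimensional epigenome-wide
    mediation analysis: cumulative psychosocial-stress scoring from
    item-level survey responses, methylation and outcome preprocessing
    (mean imputation, 3xIQR winsorization, cell-composition and batch
    residualization, medication adjustment), total-effect regression
    models, a composite-null max-P mediation scan with a mixture
    reference distribution, principal-component based quantification of
    cumulative mediation via nonparametric bootstrap, de-biased LASSO
    multivariable mediation, and genomic-feature enrichment by Fisher's
    exact test.  A synthetic-data generator with a known truth table
    makes every stage testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
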