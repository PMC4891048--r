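Package: pharmsig
Title: Drug-Sensitivity Prediction and Resistance-Gene Screening for Cell-Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pharmacogenomic pipeline for drug x cell-line
    panels. Predicts missing drug sensitivities (pIC50) by similarity-
    regularized nonnegative matrix factorization (collaborative filtering
    with cell-line cosine similarity and drug Tanimoto similarity), selects
    per-cancer-type signature genes by group-sparse-lasso regression of the
    cell-line factors onto expression features, and screens primary-
    resistance candidate genes by a multi-criteria filter integrating
    expression, copy-number, mutation-background outlier exclusion and
    discretized drug activity with Spearman sign-concordance. Includes
    ranking evaluation metrics (RMSE, concordance index, probabilistic and
    weighted-probabilistic concordance), synthetic-lethality pair mapping,
    hypergeometric gene-set enrichment, and a synthetic panel generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
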