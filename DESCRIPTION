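Package: enerflow
Title: Whole-Cell Energy Budgets from Proteomics-Constrained Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a cell's maximum ATP-generation capacity from label-free
    proteomic abundances by abundance-constrained flux balance analysis,
    calibrates the prediction against measured ATP-production and
    metabolite-exchange rates, and distributes the available ATP/GTP flux
    across energy-consuming protein classes to produce a whole-cell energy
    budget and a protein-synthesis-rate estimate. Includes rule-based
    imputation of missing label-free quantification values stratified by
    tissue-expression category, gene-protein-reaction rule evaluation with
    minsum aggregation, saturating compression of abundances into flux
    bounds, two-dimensional parameter sweeps, and synthetic-data generators
    (a toy metabolic network with analytically known ATP optima and a
    class-structured log-normal proteome) so the whole pipeline is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
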