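Package: autoqtl
Title: Automated QTL Analysis Pipelines via Genetic Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evolves quantitative trait locus (QTL) analysis pipelines --
    inheritance-model genotype re-encoding, genetics-aware feature selection,
    and a regression root (linear model, regression tree, or random forest) --
    by genetic programming under two-objective Pareto optimization of test R
    squared and an overfitting-penalizing difference score, with NSGA-II
    survival selection and a cumulative Pareto archive. Includes Shapley-value
    locus importance for Pareto-optimal pipelines, and a simulation toolkit
    for Hardy-Weinberg genotypes, additive phenotypes, and calibrated XOR
    two-locus epistasis used to benchmark detection of non-additive genetic
    variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rpart,
    stats,
    utils,
    graphics,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
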