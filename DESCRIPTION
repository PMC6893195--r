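Package: qtlprio
Title: Network-Based Prioritization of QTL Positional Candidate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks positional candidate genes inside a quantitative trait
    locus (QTL) by combining two independent lines of evidence: predicted
    functional association with trait-related gene modules, obtained from
    ensembles of linear support vector machines trained on weighted
    functional-network connectivity features, and single-SNP mixed-model
    association (EMMA-style maximum-likelihood ratio tests with an
    identity-by-state kinship random effect). Large trait gene sets are
    decomposed into modules by iterative fast-greedy community detection;
    per-gene SVM decision values are calibrated to false positive rates;
    SNP p-values are assigned to the nearest gene within a distance cutoff.
    Both evidence axes are normalized over the positional candidates and
    summed into a combined gene score, and the Pareto front of the
    two-objective space flags the best trade-off candidates. Includes a
    synthetic-fixture simulator (planted-partition networks, trait gene
    sets, inbred strain panels with a causal SNP) so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
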