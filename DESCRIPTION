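Package: rxnrank
Title: Label Ranking for Reaction Condition Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Recommends reaction conditions for new substrates by label
    ranking: models map substrate features directly to a ranking over a
    fixed set of candidate conditions instead of regressing yields.
    Implements ranking by pairwise comparison (RPC), label ranking random
    forests (LRRF) with two-stage Borda aggregation, instance-based
    Mallows (IBM) and Plackett-Luce (IBPL) rankers, and the comparator
    strategies they are usually benchmarked against (mean-yield baseline,
    yield regressor, multi-class and multi-label classifiers, k-nearest
    neighbours). Includes Borda aggregation with middle-rank imputation
    for missing labels, penalized mean-reciprocal-rank / top-1 / Kendall
    tau metrics, cross-validation and training-set masking evaluation
    protocols, adversarial (y-scramble) controls, pairwise model
    comparison tables, and a synthetic high-throughput-experimentation
    yield-table generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ChemmineR,
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
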