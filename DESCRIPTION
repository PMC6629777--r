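Package: drugsyn
Title: Classify Synergistic and Antagonistic Drug Combinations from
    Network, Phenotype and Chemical Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature engineering and gradient-boosted classification of
    two-drug combinations as synergistic or antagonistic. Implements seven
    pair-level features (indication and adverse-drug-reaction Jaccard
    overlap, biological-process semantic similarity of drug targets by the
    Wang graph measure, similarity of mode of action by sign propagation
    along all shortest paths of a signed directed protein network, the
    network separation score of the two target modules on a
    protein-protein interaction network, Tanimoto chemical-structure
    similarity, and ATC-code similarity), missing-value aware XGBoost
    classification with repeated stratified cross-validation, exhaustive
    feature-subset search, Y-scrambling permutation testing, baseline
    classifier comparison, and an interpretation layer (applicability
    domain over ATC groups, hypergeometric pathway enrichment). Seeded
    synthetic-data generators emulate every input at toy scale so the
    whole pipeline runs without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
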