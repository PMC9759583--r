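Package: flgarf
Title: Genetic-Algorithm-Optimized Random-Forest Classification of Fatty
    Liver from Gut Microbiome Genus Abundances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating gut-microbiome classifiers of
    fatty liver disease in insulin-resistant individuals. Implements a
    genetic-algorithm wrapper feature selection over genus presence masks
    with a penalized cross-validated-AUROC fitness function, random-forest
    classification with SMOTE class rebalancing and repeated stratified
    cross-validation, Gini-importance sequential feature curves, alpha and
    beta diversity (Shannon entropy, Faith's phylogenetic diversity,
    Pielou's evenness, Bray-Curtis dissimilarity with principal coordinates
    analysis), four clinical steatosis indices (FLI, NAFLD-LFS, HSI, FSI)
    as comparator predictors, and a synthetic cohort generator reproducing
    the statistical structure the analysis assumes (compositional genus
    counts with planted group effects, clinical covariates with HOMA-IR
    coupled to insulin-resistance status).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    picante,
    pROC,
    testthat (>= 3.0.0),
    vegan,
    withr,
    xgboost
Config/testthat/edition: 3
RoxygenNote: 7.3.3
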