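Package: olfclust
Title: Olfactory Phenotype Structure Discovery from Clinical Test Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and explaining phenotype structure in small
    clinical olfactory feature tables. Covers scoring of extended olfactory
    test batteries (odor-dilution sorting with Spearman-footrule scoring,
    Sniffin' Sticks TDI and diagnosis cut-offs, odor-distance, lateralization,
    enantiomer discrimination, importance-of-olfaction questionnaire),
    distribution-aware preprocessing (Tukey ladder-of-powers selection by
    D'Agostino-Pearson normality testing, chained random-forest imputation),
    unsupervised structure detection (PCA with Kaiser-Guttman retention,
    variance-weighted variable importance, k-means with silhouette-based
    cluster-number selection and bootstrap stability), computed ABC item
    categorization, nonparametric group statistics, a 17-method
    cross-validated feature-selection ensemble with ABC consolidation, and
    holdout validation by balanced accuracy. A synthetic cohort generator
    with planted cluster structure makes the whole pipeline testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    e1071,
    glmnet,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
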