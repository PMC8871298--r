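Package: breathtax
Title: Shape-Taxonomy Classification of Multi-Sensor Breath-Analyzer Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for machine-learning analysis of multi-sensor breath
    analyzer (electronic nose) time series. Raw per-measurement JSON records
    are preprocessed into equal-length, baseline-normalized response curves;
    per-sensor shape taxonomies are built by hierarchical agglomerative
    clustering of the curves under Euclidean or dynamic-time-warping
    dissimilarities with complete or Ward linkage, cut at 2-10 clusters;
    taxonomy memberships are encoded as nominal features, ranked by
    Information Gain, ReliefF or symmetrical uncertainty, and evaluated with
    Naive Bayes, linear SVM and Random Forest classifiers over repeated
    stratified train/test cycles with confidence-interval aggregation and
    ANOVA/Bonferroni configuration comparison. A synthetic breath-curve
    generator with controlled shape structure supports end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    e1071,
    randomForest,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
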