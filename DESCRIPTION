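Package: cmctraj
Title: Cardiometabolic Continuum Trajectory Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the cardiometabolic continuum (CMC) - the temporal
    sequence of hypertension, diabetes, heart disease and stroke onsets in
    one individual - from multi-disease occurrence times. Trajectories are
    encoded as 4-tuples of fractional occurrence times, clustered by
    k-means with silhouette-based selection of the number of clusters, and
    labeled by rule-based pattern definitions (EarlyHyp, LateHyp, FirstDM,
    FirstHD, Healthy). Pattern membership is then predicted from baseline
    covariates with a multiclass random forest under repeated stratified
    nested cross-validation with strictly fold-internal imputation,
    preprocessing and SMOTE oversampling, and explained with
    path-dependent TreeSHAP attributions computed on held-out folds only.
    A seeded synthetic-cohort generator emulating two study populations
    makes every stage testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    ranger,
    yaml,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
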