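Package: smdqsar
Title: Statistical Molecular Design and Reference-Model-Validated PLS QSAR
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and validating quantitative
    structure-activity relationship (QSAR) studies built on statistical
    molecular design. Provides D-optimal selection of synthesis candidates
    from combinatorial building-block libraries (Fedorov exchange),
    descriptor covariance screening with chance-correlation risk
    estimates, a NIPALS partial least squares (PLS1) engine with
    leave-one-out cross-validation, jack-knife coefficient confidence
    intervals, y-scrambling permutation tests and distance-to-model
    (DModX) applicability-domain assessment, a panel of simple reference
    (null) models with RMSEP benchmarking, and the statistical test
    scheme (Anderson-Darling, F, paired t, Kolmogorov-Smirnov,
    Mann-Whitney) used to compare predicted with measured potencies.  A
    synthetic-data generator reproduces the statistical structure of a
    designed inhibitor series so every stage of the workflow can be
    exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
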