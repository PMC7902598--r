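Package: hybridRF
Title: Hybrid Integration of Clinical and Molecular Data with Random
    Forest Synthetic Variables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for binary clinical-endpoint classification from
    heterogeneous clinical and high-dimensional molecular data. Molecular
    layers are compressed into per-patient synthetic variables - the
    out-of-bag fraction of random-forest votes for the positive class -
    which are appended to the clinical descriptors before fitting the
    final classifier (hybrid integration). The package also provides the
    two standard comparators (early feature-level merging and super
    learning over cross-validated base-model predictions with bootstrap
    bias correction), per-layer filter feature selection (Mann-Whitney
    U test, one- and two-dimensional entropy filters, SGoF multiple-testing
    correction, greedy Spearman redundancy removal, top-m capping), a
    shadow-feature all-relevant selector for clinical variables, a
    repeated stratified cross-validation harness with ACC/AUC/MCC metrics
    and paired strategy comparisons, single-feature-removal sensitivity
    analysis and recursive feature elimination, and a synthetic multi-modal
    cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    randomForest,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
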