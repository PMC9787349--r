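Package: sacq
Title: Dynamic String-Averaging CQ Method for Split Feasibility Problems
    with Dose-Volume Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Projection methods for linear feasibility problems with
    percentage-violation constraints, as they arise in fully discretized
    inverse radiotherapy treatment planning. Implements relaxed half-space
    projections, Landweber-type block operators built on the (nonconvex)
    sparsity-set projection that encodes dose-volume constraints, and the
    dynamic string-averaging CQ iteration, together with a synthetic
    two-dimensional Gaussian-kernel phantom generator, dose-volume-histogram
    evaluation, violation tracking, and file-based workflows (MatrixMarket
    matrices, YAML configuration, CSV logs) with a small command-line front
    end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
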