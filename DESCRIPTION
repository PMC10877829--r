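Package: tpaucfast
Title: Fast Estimation of the Two-Way Partial AUC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the two-way partial area under the ROC curve
    (tpAUC), the area under an empirical ROC curve restricted jointly by a
    sensitivity bound and a specificity bound. Provides a fast O(n log n)
    estimator assembled from trapezoidal full and one-way partial AUCs, the
    original O(nx*ny) trimmed Mann-Whitney U-statistic estimator as a
    reference, exact ground truth under the binormal ROC model by adaptive
    quadrature, a paired stratified bootstrap for comparing two classifiers'
    tpAUCs on the same cases, and simulation designs for estimator agreement
    and bias studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
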