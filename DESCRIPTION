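Package: ksvasc
Title: Kaiser Score with Breast Vascular Assessment for Breast MRI
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the composite breast-MRI diagnostic score KS*, which
    raises the Kaiser score of a lesion by three points when the lesion shows
    both increased ipsilateral breast vascularity and the adjacent vessel
    sign. Provides a configurable Kaiser decision tree with validation, the
    vascular assessment rules (vessel qualification, ipsilateral vessel-count
    comparison), BI-RADS band translation, a seeded synthetic lesion-cohort
    generator calibrated to published marginal counts, and the
    diagnostic-accuracy machinery used to evaluate ordinal scores:
    confusion-matrix metrics with exact fractions, ROC curves and
    Mann-Whitney AUC, the DeLong paired AUC test, Cohen's kappa with
    large-sample confidence intervals, and Pearson chi-square comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
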