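Package: chanse
Title: Pediatric Appendicitis Scoring and Diagnostic-Accuracy Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the CHANSE clinical score for suspected pediatric
    appendicitis (CRP elevation, Heel drop test, Anorexia, Nausea or vomiting,
    Shift to left, Elevated WBC; one point each) together with the comparator
    Pediatric Appendicitis Score, and a complete diagnostic-accuracy toolkit:
    2x2 tables with sensitivity, specificity, predictive values and likelihood
    ratios (Clopper-Pearson and Simel log-method confidence intervals), Woolf
    odds-ratio intervals, univariate group comparisons, empirical ROC curves
    with DeLong variance and the paired correlated-ROC Z-test, Youden-index
    cutoff selection, and threshold operating tables. A synthetic-cohort
    generator reproduces published group-conditional feature prevalences and
    laboratory distributions (Gaussian-copula dependence, truncated-normal
    labs) so the whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), pROC, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
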