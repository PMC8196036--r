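Package: ctceti
Title: Circulating Tumor Cell Endocrine Therapy Index Scoring and Trial Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the modified circulating tumor cell endocrine therapy
    index (CTC-ETI): four-aliquot CTC enumeration averaging, marker
    positivity Bio-Points and three-level score categories; Kaplan-Meier
    landmark analyses of progression-free survival with logrank and trend
    tests; rapid-progression contingency statistics with exact Fisher tests
    and Clopper-Pearson intervals; exact binomial operating characteristics
    of a two-stage analytical-validity design and simulation-based power for
    a three-category rapid-progression comparison; and a bootstrap
    train/validation ensemble (trees or logistic fits) with averaged
    validation probabilities, ROC/AUC and variable-importance tallies. A
    seedable synthetic cohort generator emulates the statistical structure
    of a metastatic breast cancer endocrine-therapy monitoring trial so that
    every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
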