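Package: patdisc
Title: Interpretable Pattern Discovery for Imbalanced Clinical Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains an interpretable pattern classifier for imbalanced
    categorical clinical data. A pattern is a set of attribute-value pairs
    together with a matching-ratio threshold, so that noisy or missing cells
    are tolerated as mismatches. Attributes are selected by chi-squared tests
    of independence, values by a class-conditional percentage heuristic, and
    the matching threshold by maximising the geometric mean of sensitivity
    and specificity (G-mean) on training data, with a Naive-Bayes-style
    log-likelihood fallback for strongly imbalanced targets. Includes a
    repeated stratified cross-validation framework with shared folds,
    training-only minority up-sampling, a fair-coin random baseline, paired
    one-sided Wilcoxon comparisons, and a seeded synthetic-data generator
    with a planted pattern for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    foreign,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    rpart,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
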