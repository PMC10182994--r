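Package: tfiperm
Title: Permutation Importance Analysis of Tilburg Frailty Indicator Items
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the absolute and relative diagnostic importance of
    the fifteen Tilburg Frailty Indicator (TFI) items for frailty syndrome
    classification in clinical cohorts. Provides a class-conditional Bernoulli
    generator for synthetic TFI cohorts, complete-case filtering and a
    4/6-1/6-1/6 randomized split, three tree-based classifiers (decision tree,
    random forest, discrete AdaBoost) with a validation protocol that balances
    true-positive and true-negative rates before preferring the lowest
    complexity, permutation feature importance with a one-tailed z significance
    test, and Bonferroni-corrected two-tailed pairwise comparisons of item
    importances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    ranger,
    rpart,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
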