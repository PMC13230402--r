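Package: cdextract
Title: Constrained-Label Language-Model Extraction of Common Data Elements
    from Clinical Free Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts categorical common data element (CDE) values from
    free-text clinical reports by scoring each allowed answer as a
    continuation of a classification prompt under a pluggable
    language-model scoring backend and selecting the most probable
    category.  Supports hierarchical CDE forms with parent-gated
    applicability, four prompt variants (default, adapted question-answer,
    few-shot, chain-of-thought), and relative-probability certainty for
    selective prediction.  Ships the complete evaluation methodology for
    such extraction systems: exact-match accuracy, micro- and
    macro-averaged precision/recall/F1, Cohen's kappa inter-rater
    agreement, certainty-threshold accuracy/coverage sweeps, and paired
    bootstrap model comparison with Bonferroni correction, together with a
    synthetic report-corpus generator with known ground truth for fully
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
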