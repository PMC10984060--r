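Package: dxeval
Title: Human Evaluation Scoring and Metric Meta-Evaluation for Generated
    Medical Diagnoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring language-model generated diagnosis lists with
    a branched human annotation instrument, combining per-diagnosis and
    per-output Likert judgments into record-level Diagnostic Accuracy and
    Diagnostic Reasoning scores on a (0,1) scale.  Implements the
    reference-based automated metrics used to evaluate such generations
    (longest-common-subsequence ROUGE, greedy-matching embedding F-scores,
    concept-identifier F-scores, conditional log-probability scores) over
    pluggable backends, and the meta-evaluation statistics that relate the
    two: rank and product-moment correlations with confidence intervals,
    the Wilcoxon signed-rank test with exact small-sample p-values,
    comparison of dependent overlapping correlations, and weighted Cohen's
    kappa for interrater agreement.  A synthetic cohort generator with a
    tunable latent quality-overlap correlation makes the full pipeline
    testable end to end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
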