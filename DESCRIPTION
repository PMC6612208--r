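Package: ahpgap
Title: Analytic Hierarchy Process and Likert-Scale Gap Analysis for
    Health Technology Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-criteria health technology assessment
    combining the analytic hierarchy process (AHP) with Likert-scale
    satisfaction surveys. Aggregates per-respondent Saaty-scale pairwise
    judgments into group comparison matrices by the weighted geometric
    mean, derives priority weights from principal eigenvectors with
    consistency-ratio screening, propagates weights through a
    goal/criteria/sub-criteria hierarchy, scores alternatives from
    operational indicator models, scores reverse-coded Likert
    questionnaires, and pairs AHP importance with satisfaction in an
    importance-satisfaction gap analysis. Includes a synthetic survey
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
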