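Package: overlapgaze
Title: Attention-Disengagement Scoring and Socio-Emotional Outcome Analysis
    for Infant Overlap-Task Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studies linking infant sleep fragmentation to social
    information processing. Implements the Overlap-task attention
    disengagement pipeline (trial scheduling with run-length constraints,
    area-of-interest construction, gaze-log segmentation, trial validity
    rules for manual 40-ms video coding and automated eye tracking, and the
    normalized dwell-time index), BITSEA questionnaire domain scoring with
    internal-consistency reliability, the group-level statistical layer
    (linear mixed models with Bonferroni post hocs and Cohen's d,
    independent-samples t-tests from raw data or published summaries,
    Pearson 2x2 chi-square tests, and correlation tables), and a synthetic
    cohort generator with censored latency distributions so the whole
    pipeline is testable end to end without access to infant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    lme4,
    lmerTest,
    emmeans,
    nlme
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
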