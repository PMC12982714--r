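Package: offloadr
Title: Simulation and Analysis of Optimal Cognitive Offloading Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing optimal-offloading experiments in
    which participants choose between internal memory and external reminders under
    varying reward, after a brief metacognitive intervention. Provides the trial
    schedule generator for the 16-trial value-based offloading task, a generative
    participant model (confidence-driven probit strategy choice, error-driven
    confidence updating from prediction/feedback practice cycles, hindsight-distorted
    confidence recall), scoring of the derived measures (forced internal/external
    accuracy, optimal and actual indifference points via a bounded psychometric fit,
    reminder bias, signed and absolute metacognitive bias, hindsight bias), the
    pre-registered exclusion cascade including MAD-based outlier rules, and the
    inferential layer (mixed 2x2 ANOVA, one-way ANOVA with linear contrast, Welch and
    pooled t tests with Cohen's d, indifference-point regressions, and noncentral-t
    power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
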