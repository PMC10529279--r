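Package: neosuction
Title: Suction Events and Heart-Rate Responses During Newborn Resuscitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing airway suctioning during delivery-room
    resuscitation of newborns. Segments suction events from typed interval
    annotations (repetitive insertions with no pause greater than 5 seconds),
    extracts pre- and post-event heart rates from monitor-derived ~1 Hz heart
    rate streams, classifies suction-related heart-rate responses (a fall
    greater than 15 percent of the pre-event heart rate, bigeminy detected
    from beat-to-beat intervals, or a fall greater than 30 bpm attributable
    to stopping positive-pressure ventilation immediately before suctioning),
    and provides the accompanying statistical layer: per-newborn descriptive
    summaries, one-sample Wilcoxon signed-rank tests, 2x2 chi-square
    mortality comparisons, and restricted-cubic-spline logistic regression
    with cluster-robust (sandwich) standard errors, Wald tests and predicted
    probability curves. A calibrated synthetic-cohort generator with known
    ground truth supports end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
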