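Package: vgchoice
Title: Value-Guided Choice Under Time Pressure: Prospect-Theory Modelling
    and ROI BOLD Timecourse Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-attribute value-guided choice experiments
    in which decision time is manipulated (speeded, free-response and delayed
    conditions). Implements prospect-theory subjective-value transforms with a
    softmax choice rule and a grid-based Bayesian estimator of the curvature
    (alpha), probability-weighting (gamma) and decision-noise (tau) parameters;
    trial-level choice regressions and condition comparisons; trial-epoched
    region-of-interest BOLD timecourse GLMs that distinguish value-sum from
    value-difference coding, with hemodynamic-response amplitude summaries and
    within-subject group statistics; and across-subject regressions linking
    value coding to choice performance. A fully seeded synthetic generator for
    task schedules, choice agents and ROI BOLD signals with known ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
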