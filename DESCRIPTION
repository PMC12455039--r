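Package: seqtte
Title: Sequential Target Trial Emulation for Longitudinal Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for emulating a sequence of nested target trials from
    longitudinal electronic-health-record tables: eligibility screening with
    new-user washout rules, a 3-month sequential trial grid on the age or
    calendar axis, baseline arm assignment, expansion of patient-trials into
    discrete 3-month person-time, propensity-score estimation and 1:1 greedy
    nearest-neighbour matching within a caliper, pooled logistic discrete-time
    hazard models for intention-to-treat and cumulative-dose per-protocol
    effects, model-based cumulative incidence with risk ratios, risk
    differences and numbers needed to treat or harm, and percentile bootstrap
    confidence intervals by resampling within matched pairs. A synthetic
    record generator with known causal structure (confounded initiation,
    sustained or discontinued exposure, discrete outcome and death hazards,
    administrative censoring) makes every stage verifiable by parameter
    recovery against closed-form oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
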