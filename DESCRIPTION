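Package: telecopd
Title: Simulation and Analysis of COPD Telemonitoring Trials with
    Personalized Alert Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying remote-monitoring interventions in chronic
    obstructive pulmonary disease (COPD). Provides a reproducible synthetic
    cohort generator for daily telemonitoring data (symptom diaries, pulse
    oximetry, heart rate, reliever use) under 2:1 randomization; a
    personalized safety-alerting engine that derives per-patient thresholds
    from run-in centiles (97th for heart rate and symptom score, 3rd for
    oxygen saturation), applies a two-day persistence rule and builds a
    clinician review queue; a symptom-based exacerbation case-definition
    classifier; and an intention-to-treat trial analysis suite (linear
    mixed-effects model with treatment-time interaction, log-binomial
    relative risks with a modified-Poisson fallback, incidence rate ratios,
    rank tests, subgroup contrasts, unequal-allocation sample size, usage
    compliance and unit-cost summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    MASS,
    sandwich,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
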