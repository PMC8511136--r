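Package: irtsim
Title: Tumor Growth Modeling and Simulation of Intermittent Radiotherapy
    Schedules for Recurrent High-Grade Glioma
Version: 0.1.0
Authors@R:
    person("irtsim", "developers", email = "irtsim@example.org",
           role = c("aut", "cre"))
Description: Implements a two-compartment exponential tumor growth model with
    radiation surviving fraction and exponentially decaying systemic-therapy
    kill rate, calibrated to longitudinal tumor-volume measurements.
    Provides constrained multistart fitting with a population-level growth
    rate grid search, bootstrap uncertainty estimation, AIC-based
    parameter-sharing comparison and sensitivity ranking; simulation of
    hypofractionated and intermittent radiotherapy schedules including a
    progression-triggered boost; time-to-progression scoring with
    Kaplan-Meier, logrank, rank-sum and correlation analyses plus gEUD
    dosimetry summaries; and a synthetic virtual-patient cohort generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
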