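Package: arcqa
Title: Virtual Patient-Specific QA for Single-Isocenter SRS Arcs
Version: 0.1.0
Authors@R:
    person("arcqa", "developers", email = "arcqa@example.org", role = c("aut", "cre"))
Description: Tools for virtual (measurement-free) patient-specific quality
    assurance of volumetric modulated arc therapy plans for single-isocenter
    stereotactic radiosurgery. Reads and writes a dynamic-arc subset of DICOM
    RTPLAN, computes eighteen plan-complexity metrics from multileaf collimator
    control-point trajectories under a delivery-time model, performs 2D
    gamma-index analysis, generates calibrated synthetic QA cohorts, reduces
    feature multicollinearity by Spearman/Ward clustering, trains a weighted
    random-forest regressor of the gamma passing rate under a hybrid
    time-series/stratified protocol with leakage-safe scaling, calibrates a
    pass/fail threshold limit, and evaluates regression, classification,
    partial-dependence interpretability, and expected QA-workload reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
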