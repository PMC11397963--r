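Package: imugait
Title: Simulation, Event Detection, Parameterisation and Classification of
    Joint-Impaired Gait from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reproducible pipeline for wearable-sensor gait analysis under
    simulated knee and ankle joint impairment. Provides a calibrated synthetic
    gait generator (sagittal thigh/shank angle waveforms at 50 Hz plus
    pressure-walkway footfall records with ground-truth events), heel-strike
    and toe-off detection from shank angular velocity via topographic peak
    prominence, extraction of 21 inertial and 25 walkway gait parameters per
    gait cycle including temporal and spatial symmetry ratios, recursive
    feature elimination with subject-grouped cross-validated classification
    (linear support vector machine, random forest, gradient boosting), and
    nonparametric repeated-measures post-analysis (Friedman test, paired
    Wilcoxon signed-rank tests with Bonferroni correction).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
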