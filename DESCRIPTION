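Package: forcepsml
Title: Segmentation and Pattern Recognition for Bipolar-Forceps Tool-Tissue Forces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing tool-tissue interaction
    forces recorded by a sensorized bipolar forceps at 20 Hz. Provides a
    seeded synthetic-recording generator calibrated to published operating
    room duration statistics, point-wise active/idle segmentation of force
    traces with a 1D U-Net ('T-U-Net'), 29 hand-crafted time-series features
    per force segment, surgeon skill (Expert/Novice) and surgical task
    (Coagulation/non-Coagulation) recognition with an InceptionTime-style
    convolutional network ('FTFIT'), LSTM and gradient-boosting baselines,
    a hybrid logistic head on learned plus engineered features, and
    evaluation reports (weighted F1, macro-AUC, cross-validation, gauge-style
    expert comparison). Neural networks are trained with a compact built-in
    engine on BLAS matrix operations for fully deterministic CPU runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    xgboost,
    class,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
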