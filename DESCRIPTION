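Package: cuffless
Title: Cuffless Blood Pressure Estimation from Multiparametric Wearable Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested, reproducible pipeline for estimating systolic and
    diastolic blood pressure from multiparametric wearable recordings (two
    ECG channels, a phonocardiogram, two thoracic-impedance channels and an
    activity channel) combined with subject demographics. Includes a
    synthetic-data generator with known ground-truth hemodynamics, signal
    quality screening with a 300-second lookback / 60-second window
    association rule, ECG R-peak detection and ensemble averaging, S1/S2
    heart-sound segmentation, impedance-pneumography respiration features,
    dual-observer reference reconciliation on the 2-mmHg grid, JNC 7
    classification, impurity-based feature selection, seeded regression-tree
    ensembles with a demographics-only baseline, and the full evaluation
    machinery: MAD/MAPD/RMSE, condition-stratified reports, Bland-Altman
    agreement statistics, paired-bootstrap RMSE model comparison and
    bootstrap MAD confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    rpart,
    xgboost,
    jsonlite,
    yaml,
    data.table,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
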