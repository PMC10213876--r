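Package: qtiholter
Title: Individualized QT Interval (QTi) Analysis from 24-Hour Holter ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving the individualized QT interval (QTi) from
    long-term ambulatory (Holter) electrocardiograms. Recordings are reduced
    to 30-second averaged beat templates, the T-wave end is located by the
    tangent method, and each subject's QT-RR relation is fitted by linear
    regression so that QTi (the QT interval at an RR interval of 1,000 ms)
    and the QT-RR slope can be read off the fit. Includes a synthetic Holter
    generator with known QT-RR ground truth calibrated to published long-QT-
    syndrome cohort parameters, ISHNE (.ecg) file input/output, and
    diagnostic evaluation (empirical ROC curves, DeLong comparison of
    correlated AUCs, Youden cut-offs, likelihood ratios, paired
    repeat-recording comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
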