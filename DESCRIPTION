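Package: mpus
Title: Multiparametric Ultrasound Decision Pipeline for Inconclusive Focal Liver Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of contrast-enhanced ultrasound (CEUS) late-phase
    time-intensity curves by exponential washout fitting, the time-averaged
    AREA washout statistic with its -19.3 dB operating cutoff, a fixed
    three-step binary decision tree (liver fibrosis, washout, arterial
    enhancement pattern) that calls malignancy and lesion type for focal
    liver lesions left inconclusive by CEUS, and the accompanying evaluation
    statistics (confusion metrics, ROC/AUROC with Youden cutoff, group and
    proportion tests, lesion-parenchyma regression). A seeded synthetic
    cohort generator emulating the statistical structure of a 91-lesion
    clinical series makes the full simulate-quantify-classify-evaluate
    pipeline reproducible without patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
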