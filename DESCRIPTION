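Package: SpineScreen
Title: Vertebral Morphometry and Acute Compression-Fracture Screening Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating screening strategies for acute vertebral
    compression fractures on sagittal spine label masks. Provides a parametric
    sagittal spine phantom generator (trapezoidal vertebral bodies with wedge,
    biconcave and crush deformities, cortical step-offs and break fissures),
    automated anterior/middle/posterior height measurement with height-loss-ratio
    (HLR) computation and Genant semiquantitative grading, preprocessing stages
    (Hounsfield-unit windowing, cortical contour extraction, patch
    standardization), a deterministic contour-irregularity detector and a
    calibrated stochastic detector emulator, OR/AND fusion of binary detectors,
    and vertebra-wise evaluation statistics (confusion matrices, sensitivity,
    specificity, accuracy and precision with Wilson score confidence intervals,
    and ROC/AUC utilities).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    tiff,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
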