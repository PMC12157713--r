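Package: septanose
Title: Exhaled-Breath Electronic-Nose Analysis for Early Sepsis Detection
    Under Variable Inspired Oxygen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal processing and classification pipeline for metal-oxide
    semiconductor (MOS) electronic-nose measurements of exhaled breath
    collected during mechanical ventilation. Implements ventilator-synchronized
    breath-sampling simulation, bivariate (time x FiO2) correction surfaces
    built from clean-air calibration series to remove the inspired-oxygen
    confounder from sensor response curves, curve-shape feature extraction with
    interquartile-range outlier screening, and per-timepoint leave-one-out
    classification of control versus endotoxemic (LPS) subjects with principal
    component reduction, logistic-regression and decision-tree models, and
    Wald confidence intervals. A synthetic-data generator emulating the sensor
    physics and the cohort's physiology makes every stage testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    rpart,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
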