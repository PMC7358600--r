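Package: wodrec
Title: Recognition of Functional-Fitness Drills from Wearable Inertial Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing functional-fitness drills (clean & jerk,
    american swing, box jump, burpee) and the transition phases between them
    within a continuous workout, from multi-sensor accelerometer and gyroscope
    timeseries. Implements sliding-window segmentation with majority labeling,
    time- and frequency-domain feature extraction, a grid of SVM and k-nearest
    neighbour classifiers, k-fold and leave-one-subject-out evaluation with
    confusion-matrix metrics and one-vs-rest ROC/AUC, minimum-redundancy
    maximum-relevance (mRMR) feature ranking, sensor-subset sensitivity
    experiments, and a seeded synthetic-workout simulator so the full pipeline
    can be exercised end to end without access to a recorded dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
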