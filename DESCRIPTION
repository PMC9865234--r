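Package: wristposture
Title: Wrist Posture Classification from Paired Hand and Wrist Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates binned wrist posture (five flexion/extension classes and
    three radial/ulnar-deviation classes) from two 6-degree-of-freedom inertial
    measurement units worn on the hand and wrist. Provides a forward-kinematic
    synthetic-cohort generator emulating bench-top occupational tasks, zero-lag
    Butterworth preprocessing with sliding-window restructuring, range-of-motion
    histogram resampling for class balance, a small convolutional neural network
    window classifier with subject-specific refinement, and leave-one-subject-out
    evaluation with Cohen's kappa agreement statistics and contingency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
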