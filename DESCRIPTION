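Package: atriaPET
Title: Automated Atrial Volume Estimation from Dynamic Cardiac PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fully automated estimation of left and right atrial volumes from
    a single non-gated dynamic cardiac PET scan. Voxel-wise first-pass
    indicator-dilution analysis yields parametric images of bolus arrival
    time (centroid time, t_mid) and area under the curve (AUC); cluster
    analysis of time-activity curves provides arterial and venous input
    functions; a basis-function implementation of the single-tissue
    compartment model for O-15 water produces myocardial blood flow,
    perfusable tissue fraction and blood-volume maps used to segment both
    ventricles; the atria are then isolated from the blood pool with
    bolus-timing gates, an outflow-tract split of the aorta and tube
    detection for the superior vena cava. A synthetic 4D cardiac phantom
    generator with known geometry, bolus timing and kinetics supports
    validation and test-retest repeatability experiments (repeatability
    coefficient, coefficient of variation, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
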