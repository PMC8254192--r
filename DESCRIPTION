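Package: sctqa
Title: Quality Assessment of Synthetic CT for MRI-Only Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for independent quality assessment of synthetic CT (sCT)
    images in MRI-only radiotherapy of the pelvis, using the on-treatment
    cone-beam CT (CBCT) as the reference. Implements cropping of paired
    sCT/CT/CBCT volumes to the sCT body outline and water filling of
    transient air-pocket discrepancies, population-based CBCT Hounsfield
    unit to electron/mass density calibration curves, the binned median
    absolute error (MeAE) statistic with an action-level flag, a
    patch-based multi-atlas sCT synthesizer, markerless 6-DOF rigid
    bone-match registration for image guidance offset statistics, and a
    pelvic phantom generator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
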