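Package: petkin
Title: Tracer Kinetic Quantification for Dynamic Brain PET
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification of reversible radioligand binding from dynamic
    brain PET with arterial blood sampling. Builds metabolite-corrected
    arterial input functions from blood and HPLC parent-fraction tables,
    estimates total distribution volume (VT) with one- and two-tissue
    compartment models and with Logan and MA1 graphical analyses, and
    estimates non-displaceable binding potential (BPND) with the original
    multilinear reference tissue model (MRTMo), indirect VT ratios and
    SUVR windows. Includes model-selection statistics (AIC, MSC, F test),
    time-stability (scan truncation) analysis, voxelwise parametric BPND
    mapping, and a seeded synthetic-subject generator with known ground
    truth so every estimator can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
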