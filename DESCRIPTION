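Package: phloempet
Title: Compartmental Modelling of Carbon-11 PET Time-Activity Curves in
    Plant Shoots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies phloem transport from dynamic positron emission
    tomography (PET) of thin plant shoots. Provides forward simulation of
    a four-compartment tracer model over consecutive stem regions driven
    by a measured input time-activity curve, global calibration of the
    transport parameters (phloem front speed, leakage-retrieval, storage
    and efflux exchange rates) by shuffled complex evolution, local
    sensitivity and collinearity-index identifiability analysis,
    Monte-Carlo positron-annihilation geometry for thin cylindrical
    stems, a synthetic time-activity-curve and 4D phantom generator for
    validation, and descriptive summaries of fitted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
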