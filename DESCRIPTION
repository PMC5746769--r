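Package: wlrs
Title: White Light Reflectance Spectroscopy Modeling and Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward modeling and inversion for white light reflectance
    spectroscopy (WLRS), a label-free optical biosensing technique based on
    normal-incidence thin-film interference from Si/SiO2 (and Si3N4) layer
    stacks. Provides the Abeles recursion and the explicit two-layer closed
    form for multilayer reflectance, raw-spectrum normalization against
    reference and dark spectra, interference-extremum location and tracking,
    Levenberg-Marquardt full-spectrum fitting of layer thicknesses with
    sub-Angstrom resolution estimation, and an assay-analysis layer covering
    Langmuir binding and polymer swelling sensorgram simulation,
    endpoint/initial-rate quantification, four-parameter logistic calibration
    with limit-of-detection estimation, chip regeneration statistics, and
    multi-band scanning simulation. A synthetic-data generator makes every
    stage testable without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
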