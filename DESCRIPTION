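Package: epinir
Title: Near-Infrared Calibration of Passion-Fruit Epicarp Hardness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics workflow for predicting the outer (F1) and inner
    (F2) epicarp hardness of passion fruit from near-infrared diffuse
    reflectance spectra (10,000-4000 cm-1). Implements peak-force extraction
    from puncture force-displacement curves, SPXY calibration/prediction
    partitioning on joint spectral-response distance, moving-average and
    mean-centering preprocessing, three feature-wavelength selectors over a
    shared partial least squares engine (competitive adaptive reweighted
    sampling, the successive projections algorithm, and uninformative
    variable elimination), grid-searched random forest and genetic-algorithm
    tuned support vector regression, and R2/RMSE/RPD model assessment. A
    seeded synthetic-data generator emulates the statistical structure of the
    study design (120 fruits over six storage batches, water/pectin/cellulose
    absorption bands) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mixOmics
Config/testthat/edition: 3
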