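Package: discassay
Title: Rotating-Disc Microfluidic Flow Modelling and Extracellular-Vesicle
    Protein Assay Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the fluid mechanics and measurement analytics of
    centrifugal (lab-on-a-disc) bead assays for extracellular-vesicle (EV)
    surface proteins. Provides closed-form rotating-frame physics (centrifugal,
    Coriolis and gravitational body-force densities, centrifugally driven
    channel flow, Ekman and Stokes numbers, cylindrical-pore membrane
    hydraulics), a steady incompressible rotating-frame flow solver on a
    staggered grid with a Brinkman porous-membrane layer (coarse 3D and
    depth-averaged 2D modes), flow diagnostics (edge-region speeds, mirror
    asymmetry, inlet-to-outlet bypass, membrane flux), compartment models of
    washing efficiency and fluid retention, and an assay-statistics pipeline
    (median-intensity summarisation, isotype- and CD63-normalised marker
    metrics, blank + 3 sigma detection limits, logistic risk scores with ROC,
    linear discriminant analysis with leave-one-out cross-validation and
    stratified bootstrap standard errors). Synthetic-data generators with
    planted ground truth supply bead-event tables, titration series and an
    82-sample four-group cohort for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
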