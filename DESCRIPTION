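Package: ocupulse
Title: Non-Invasive Ocular Rigidity from Pulsatile Choroidal Thickness in
    OCT Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the Friedenwald ocular rigidity coefficient from
    dynamic optical coherence tomography (OCT) B-scan video of the optic
    nerve head. Segments the retinal pigment epithelium and the
    choroidal-scleral interface in every frame with a graph search over
    intensity inflection points, extracts the pulsatile choroidal
    thickness waveform (outlier removal, anti-aliased resampling to a
    uniform grid, heart-rate band-pass, mean peak-to-valley amplitude),
    converts the thickness pulse to an ocular volume change under a
    thin-spherical-shell model, and combines it with dynamic contour
    tonometry readings via Friedenwald's pressure-volume relation.
    Includes corneoscleral stiffness parameters from air-puff corneal
    deformation exports, a paraxial schematic-eye axial-length
    derivation, cohort statistics (group comparison, correlation,
    normality, Bland-Altman agreement), and a synthetic-data generator
    producing B-scan stacks and cohort tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    MASS,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
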