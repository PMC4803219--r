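Package: pulmomech
Title: Lung Mechanics from Ventilator Signals, AFM Nanoindentation and
    Alveolar Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of murine lung mechanics across three
    measurement modalities. Extracts static and dynamic elastances from
    volume-controlled ventilation recordings by the end-inspiratory
    airway occlusion method (cannula pressure correction, occlusion
    detection, piecewise-linear inflection-point fitting, chest-wall
    decomposition); computes Young's modulus of decellularized lung
    extracellular matrix from atomic-force-microscopy force curves via
    the pyramidal Hertz contact model, the complex shear modulus G*(f)
    from multifrequency indentation records, and fits the two power-law
    viscoelastic model A*(i f)^alpha + B*(i f)^(3/4); measures alveolar
    mean linear intercept from histology sections by vessel removal,
    binarization, skeletonization and probe-grid intercept counting; and
    reproduces the study-level group statistics (gated t/Mann-Whitney,
    two-way ANOVA with and without repeated measures, Holm-Sidak post
    hoc). A synthetic-data module simulates all three modalities with
    known ground truth so every stage is verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    minpack.lm,
    car,
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
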