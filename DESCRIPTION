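Package: guvepore
Title: Electrodeformation, Poration and Actin-Cortex Mechanics of Giant Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of electroporation experiments on giant
    unilamellar vesicles (GUVs). Detects vesicle contours in bright-field or
    confocal image sequences, fits ellipses to obtain deformation-ratio and
    projected-area time series, extracts exponential relaxation times and
    dye-uptake (resealing) kinetics, normalizes per-pulse area loss and
    photobleaching-corrected actin fluorescence, and evaluates a closed-form
    force balance on a membrane-bound actin cortex (Schwan transmembrane
    voltage, filament count, mesh-size stretch, mechanical and electrophoretic
    forces). Includes a synthetic-data generator that emulates the imaging and
    kinetic structure of such experiments so the full pipeline is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
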