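Package: soleheat
Title: Bioheat Simulation and Sensor Calibration for Smart-Insole Plantar Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Steady-state Pennes bioheat modelling of a layered foot, sock,
    insole and shoe stack with embedded subcutaneous lesions (inflammation or
    ischemia), a virtual eight-point insole temperature-sensor array with a
    detectability rule, and a closed-form one-dimensional multilayer solution
    used as a verification oracle. Also implements the companion sensor
    calibration mathematics: piezoelectric charge-force fitting (d33, figure
    of merit, force-to-pressure), and amperometric glucose calibration from
    cyclic-voltammetry traces (peak extraction, linear-range identification,
    area-normalised sensitivity, IUPAC-style limit of detection), exercised on
    seeded synthetic data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
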