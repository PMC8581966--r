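Package: ionchem
Title: Gas-Phase Ion Chemistry Workflows for Isomeric Anion Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating isomeric deprotonated small molecules
    (e.g. thyroid-hormone anions) by combining infrared multiple photon
    dissociation (IRMPD) action spectroscopy, traveling-wave ion-mobility
    collision-cross-section (CCS) calibration, projection-approximation CCS
    from 3-D structures, Fourier-transform ion cyclotron resonance
    ion-molecule reaction kinetics with average-dipole-orientation collision
    theory, and gas-phase acidity bookkeeping. Includes seeded synthetic-data
    generators that emulate each experimental stage so the whole chain can be
    exercised end to end, molecular-formula exact-mass arithmetic, and report
    assembly across stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
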