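Package: viscogel
Title: Design of Viscoelastic Hydrogel Substrates by the Cell-Perceived
    Deborah Number
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the in-silico design of dextran-permeated agarose
    hydrogels as viscoelastic cell-culture substrates. Implements the
    adapted standard linear solid (aSLS) model of the epsilon-dot
    (constant strain rate) compression test, extraction of viscoelastic
    descriptors (equilibrium, instantaneous and apparent moduli,
    relaxation time) by non-linear least squares, a coupled
    mechanics-transport model of hindered dextran diffusion through the
    gel network (Brinkmann drag, rubber-elasticity mesh size, zero-order
    solute sink) solved by the method of lines, and the Deborah-number
    design step that matches gel relaxation times to the focal-adhesion
    timescales of adherent cells. Includes seeded synthetic-data
    generators, cell morphometrics (cell shape index, YAP
    nuclear/cytosolic ratio) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
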