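Package: emhdflow
Title: Electro-Magneto-Hydrodynamic Peristaltic Transport of Gold-Blood Nanofluid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulator for peristaltic transport of a gold-nanoparticle blood
    nanofluid in an asymmetric micro-channel under combined electroosmotic and
    magnetic forcing, in the long-wavelength, low-Reynolds-number (lubrication)
    limit. Couples the stream function, temperature, nanoparticle volume
    fraction and motile-microorganism density through a ten-state two-point
    boundary-value problem with a Debye-Hueckel electric-double-layer body
    force, shape-dependent effective mixture properties, Buongiorno
    thermophoresis/Brownian-motion terms, an Arrhenius activation-energy
    reaction and gyrotactic bioconvection. Provides a fourth-order Lobatto
    collocation solver with parameter continuation, an independent
    finite-difference Newton oracle, closed-form linear-limit solutions,
    post-processing (frame transformation, wall shear stress, parameter
    sweeps) and a configuration-driven command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
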