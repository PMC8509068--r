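Package: nanoscatter
Title: Scattering and Aerodynamic Characterization of Polymer-Drug Nanosuspensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Physico-chemical characterization pipeline for reconstituted
    polymer-drug nanosuspensions, developed around hyaluronic-acid (HYA)
    coated dexamethasone (DEX) nanoparticles. Implements closed-form
    small-angle scattering models (Guinier, high-q power law, polyelectrolyte
    correlation peak, polydisperse core-shell sphere), Bragg indexing against
    an orthorhombic lattice, quantification of bound versus unbound polymer by
    spectral decomposition, mucin-stability testing by non-negative linear
    combination, dynamic light scattering inversion with viscosity-corrected
    Stokes-Einstein sizing, and cascade-impactor aerodynamics (MMAD, GSD,
    emitted and fine-particle fractions). Seeded synthetic-data generators
    with attached ground truth support recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
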