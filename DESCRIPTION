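Package: osmotip
Title: Osmotic Model of Pollen-Tube Tip Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulator of osmotically driven tip growth in pollen
    tubes. Couples osmotic water entry through an apical permeable zone, solute
    accumulation and dilution, an algebraic turgor balance, viscous expansion of
    the apical pectin film with calcium-dependent hardening, and osmosensor
    feedback on wall deposition. Includes a fixed-step integrator with burst and
    arrest detection, declarative perturbation scenarios (steps and sinusoids)
    reproducing the classical simulation regimes, a stability screen over the
    nine candidate sensor couplings, a calcium-to-hardening law, and a
    plasmolysis retraction model with nonlinear least-squares recovery of
    osmotic permeability and osmotic-zone length from retraction time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
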