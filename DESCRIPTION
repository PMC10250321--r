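Package: cellmech
Title: Cell Mechanics and Motility Analysis for Macrophage Mechanobiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the standard linear viscoelastic solid model to micropipette
    aspiration creep curves, estimates reduced Young's moduli from ferrule-top
    nanoindentation load-indentation curves via the Hertz spherical contact
    model with automatic contact-point detection, and quantifies chemotactic
    motility (velocity, directionality) and wound-closure time courses.
    Includes seeded synthetic-data generators (creep curves, indentation
    curves with pre-contact baselines, biased persistent random-walk
    trajectories) so every fitting stage can be validated by parameter
    recovery, plus delimited-text readers and writers with explicit unit
    handling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
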