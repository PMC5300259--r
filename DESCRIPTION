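Package: nmdarfx
Title: Functional Characterization Pipeline for NMDA Receptor Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for voltage-clamp characterization of NMDA
    receptor (GluN1/GluN2A) variants: Hill concentration-response fitting for
    agonist potency (glutamate, glycine) and allosteric inhibition (protons,
    zinc, magnesium), bi-exponential deactivation kinetics with weighted time
    constants and charge transfer, MK-801 open-channel block onset fitting, and
    relative open-probability inference from block kinetics and MTSEA
    potentiation. Includes a deterministic Markov/ODE receptor gating simulator
    that generates annotated synthetic current traces under arbitrary
    solution-exchange protocols, so every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
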