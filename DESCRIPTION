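Package: ctpress
Title: Interface Pressure Analysis for Medical Compression Textiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts and validates the interface pressure delivered by tubular
    knitted compression textiles worn on the lower leg. Reduces fabric tensile
    tests to orthotropic moduli, converts shear-wave elastography readings to
    soft-tissue Young's moduli and neo-Hookean constants, represents legs as
    stacked cross-section contours, and solves a quasi-static Laplace-law
    membrane equilibrium on a Hertz-contact tissue foundation to obtain
    per-position pressures, fabric tensions and indentations. Includes the
    Hertz rigid-versus-soft pressure-diversity ratio, deviation-ratio and
    paired-comparison validation statistics, and seeded synthetic generators
    for legs, fabric batches, elastography records and pressure-meter readings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
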