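Package: ldmprint
Title: Process Models for Low-Temperature Extrusion Printing of Gelatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the extrusion stage of low-temperature deposition
    manufacturing (LDM) of thermo-sensitive gelatin solutions: power-law
    (pseudoplastic) rheology with fitting and gel-point detection from
    viscometry ramps and oscillatory moduli, natural-convection heat-transfer
    correlations (Grashof/Prandtl/Nusselt), a quasi-1D non-isothermal
    power-law flow simulator of the barrel-taper-nozzle channel with a
    bang-bang heater thermostat, and the extrusion-speed/print-speed
    line-width matching model with its regression correction and optimal
    inlet-velocity solver. Includes seeded synthetic-data generators for
    every input the analyses need.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
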