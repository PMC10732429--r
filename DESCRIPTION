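Package: merkelcell
Title: Biophysical Whole-Cell Simulation of Merkel-Cell Mechanotransduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic whole-cell model of a Merkel cell: Hodgkin-Huxley
    style voltage-gated K+ and Ca2+ channels, a stress-gated four-state Piezo2
    channel, plasma-membrane pumps, cotransporters and exchangers, endoplasmic
    reticulum and mitochondrial Ca2+ stores with IP3/ryanodine receptor gating,
    osmotic volume mechanics of the actin cortex, and Ca2+-dependent vesicle
    exocytosis. The coupled stiff ODE system is integrated with deSolve;
    stimulus protocols (current pulses, high-K+ solution swap, hypotonic shock,
    indentation ramp-and-hold) are provided as runnable scenarios together with
    trace summaries of membrane potential, Ca2+ transients and transmitter
    release.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
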