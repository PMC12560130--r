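Package: plasmotaste
Title: Cross-Reactive Plasmonic Sensor Array Simulation and Chemometric
    Fingerprinting of Liquids
Version: 0.1.0
Authors@R:
    person("Plasmotaste", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a 24-element cross-reactive plasmonic (LSPR) sensor
    chip read out by hyperspectral transmission imaging, and provides the
    full analysis pipeline for "artificial taste" liquid fingerprinting:
    frame sectioning and reference normalisation into transmission spectra,
    smoothing-spline extraction of the plasmonic transmission minimum,
    assembly of 24-element resonance-shift fingerprints against a rolling
    deionised-water baseline, Langmuir-type adsorption kinetics ("on-curve")
    fitting, and chemometric classification of liquid samples by PCA,
    stratified linear discriminant analysis and two-way hierarchical
    clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
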