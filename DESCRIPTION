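Package: bathyspec
Title: Photostate Analysis of Bathy Phytochrome Absorption Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative photostate analysis for bathy phytochromes from
    UV/Vis absorption spectra. Decomposes photostationary Q-band spectra
    into Pr/Pfr fractions by two-component spectral unmixing against pure
    Pr and Pfr reference spectra modelled as Gaussian band superpositions,
    simulates the underlying two-state photocycle (photoconversion plus
    thermal dark reversion), fits mono- to tri-exponential dark-reversion
    kinetics with half-life extraction, and maps Pr fractions onto
    predicted active-autokinase proportions. A seeded synthetic-spectrum
    generator with presets for six bathy phytochromes makes every pipeline
    stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
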