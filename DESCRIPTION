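Package: subglottalsim
Title: Simulation and Analysis of Subglottal Acoustic Interactions in
    Excised Larynx Phonation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In-silico counterpart of excised-larynx experiments comparing
    anechoic and resonant subglottal tracts. Provides a synthetic glottal
    flow source with phenomenological source-tract (Level 2) interaction
    effects, one-dimensional lossy waveguide models of the subglottal
    space, a simple-source radiation model, the measurement and signal
    processing pipeline (impulse-averaged frequency responses, calibrated
    sound pressure levels with 'fast' time weighting, autocorrelation
    pitch tracking, phonation onset/offset threshold detection, inverse
    filtering by numerical integration), and log-linear regression of
    phonation threshold pressures across subglottal conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
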