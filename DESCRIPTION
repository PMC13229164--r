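Package: po210assay
Title: Alpha-Spectrometric Determination of Polonium-210 in Urine Bioassay
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Complete calculation chain for tracer-based (209Po isotope
    dilution) alpha-spectrometric determination of 210Po activity
    concentration in 24-hour urine samples, as used in occupational
    radiation biomonitoring of workers handling naturally occurring
    radioactive materials. Reads alpha spectra (IAEA SPE ASCII dialect or
    two-column text), performs energy calibration and region-of-interest
    integration, derives the reagent-blank constant K from blank series,
    computes tracer-normalized activity concentrations with a GUM-style
    uncertainty budget, Currie-type minimum detectable activity
    concentrations, tracer recovery, precision and proficiency-testing
    statistics (z-score, bias, En number), spectrometer stability charts,
    worker-level excretion reporting, and a Poisson spectrum/campaign
    simulator with known truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
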