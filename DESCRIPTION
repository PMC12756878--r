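Package: oxygraphR
Title: Precision OXPHOS Analysis of High-Resolution Respirometry Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of closed-chamber oxygraph oxygen traces acquired under
    substrate-uncoupler-inhibitor titration (SUIT) reference protocols.
    Converts oxygen concentration time series to background-corrected
    volumetric oxygen flux, maps titration marks onto named pathway and
    coupling control states (leak, OXPHOS, electron-transfer capacity),
    applies residual-oxygen-consumption baseline correction, fatty-acid
    oxidation subtraction, cytochrome-c integrity testing, chemical-background
    calibration for the Complex IV assay, and non-steady-state corrections.
    Derives coupling control efficiencies, flux control ratios, pathway
    additivity indices and bioenergetic profiles, compares technical repeats
    with symmetric (inverted) regression, and forward-simulates complete
    protocol runs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'protocols.R'
    'flux.R'
    'states.R'
    'corrections.R'
    'bioenergetics.R'
    'oxygraphR-package.R'
    'regression.R'
    'simulate.R'
    'pipeline.R'
    'reference-data.R'
    'trace-io.R'
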