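Package: sonarbeam
Title: Biosonar Beam-Pattern Estimation from Hydrophone Arrays
Version: 0.1.0
Authors@R: person("sonarbeam", "developers", role = c("aut", "cre"),
    email = "sonarbeam@example.org")
Description: Tools for estimating the transmission beam pattern of
    echolocating toothed whales from multichannel hydrophone-array
    recordings. Implements circular-piston directivity mathematics,
    synthetic rendering of clicking piston sources approaching an array,
    click detection and energetics (energy flux density, centroid
    frequency, inter-click intervals and buzz classification),
    arrival-time-difference localization, apparent-source-level radiation
    patterns from linear arrays, energy-surface beam-axis estimation and
    Monte-Carlo piston fitting on star-shaped arrays, virtual-source
    error simulations, click-synchronized tag echograms, and acoustic
    field-of-view statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
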