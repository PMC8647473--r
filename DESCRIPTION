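Package: caproext
Title: Electron and Carbon Bookkeeping for Extractive Chain Elongation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative analysis of lactate-based chain elongation to
    medium-chain carboxylates (MCC) in two-phase reactors with an in-situ
    vegetable-oil extraction layer. Provides a compound registry with
    degree-of-reduction (electron-equivalent) and carbon-mol conversion
    algebra, Henderson-Hasselbalch acid speciation, liquid-liquid extraction
    performance metrics (distribution ratio, partition coefficient, recovery,
    specificity), MCC-enriched-oil composition reports, period-level CSTR
    performance accounting (production and extraction rates, electron and
    carbon selectivities, conversion efficiency, acid-dose metrics, balance
    closure), and a two-phase fermentation simulator with
    undissociated-acid product inhibition that generates synthetic reactor
    time series for end-to-end testing of the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
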