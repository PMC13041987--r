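Package: tissuecure
Title: Curation of Segmented and Tracked Epithelial Time-Lapse Movies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Headless toolkit for curating segmented and tracked 2D
    time-lapse movies of confluent epithelia. Provides a label-movie data
    model with validity checks, lossless TIFF/CSV/JSON readers and writers,
    frame-to-frame cell tracking by linear assignment with gap closing and
    division hypotheses, rule-based flagging of suspicious tracks, scripted
    correction operators (merge, seeded split, junction drawing, track
    edits) with automatic local relinking, detection and probability-map
    filtering of division and extrusion events, cell- and track-scale
    feature measurement, before/after curation-quality metrics, and a
    synthetic confluent-epithelium simulator with invertible error
    injection so the whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
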