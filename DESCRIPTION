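Package: cftrscreen
Title: High-Content Imaging and Plate-Based Screening Analysis for CFTR
    Corrector Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for two compound-screening readouts used in
    F508del CFTR corrector discovery: a high-content imaging arm that segments
    nuclei and cells from two-channel fluorescence fields, derives plasma-membrane
    (2 px) and perinuclear (5 px) ring regions of interest, and reports per-well
    mean fluorescence for the plasma-membrane, perinuclear and whole-cell
    compartments; and a 384-well plate fluorescence arm implementing fold-increase,
    percent-viability and viability-normalized fold-increase scoring against
    in-plate controls. Screen-level quality control (per-plate Z factor with
    mean +/- SEM aggregation) and hit calling by a 3-standard-deviation rule are
    provided, together with ground-truthed synthetic-data generators for both
    input kinds so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
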