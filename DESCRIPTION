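Package: spindleq
Title: Quantitative Analysis of Acentrosomal Spindle Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying fluorescence microscopy of acentrosomal
    (meiotic) spindles. Implements correction, normalization and
    multi-model fitting of fluorescence recovery after photobleaching
    (FRAP) traces with a two-population half-time parameterization and
    AICc model selection; pole-to-pole intensity line profiles with
    ten-bin medians and a sub-polar/equator ratio statistic; ROI-based
    background-subtracted spindle-pole intensity and chromosome-spread
    measurement with their log-intensity correlation; and synthetic-data
    generators (FRAP trace ensembles, two-channel spindle images,
    congression datasets) that make every stage testable without raw
    microscopy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    utils,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    yaml,
    jsonlite,
    tiff,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
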