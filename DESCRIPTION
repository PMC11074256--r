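Package: vegrf
Title: Object-Based Vegetation Classification with Gain-Ratio Trees and a
    Weighted-Feature Random Forest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for object-based classification of vegetation in
    multispectral imagery. Generates synthetic labelled scenes, extracts an
    85-feature object inventory (spectral statistics, geometry, grey-level
    co-occurrence and difference-vector texture, vegetation indices), trains
    a random forest of C5.0-style gain-ratio decision trees with
    positive-class-weighted feature subsampling for imbalanced classes, and
    assesses thematic accuracy (overall, producer's and user's accuracy,
    kappa). Also provides plant-diversity indices (Shannon diversity,
    Margalef-style richness, Simpson dominance), the enhanced vegetation
    index (EVI), and dimidiate-pixel fractional vegetation cover estimation
    with determination-coefficient and RMSE validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
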