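Package: emospace
Title: Multi-Source Metric Multidimensional Scaling of Semantic Emotion Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Maps the semantic space of discrete emotion concepts from
    multi-aspect visual-analogue ratings (valence, arousal, control, utility,
    each 0-100 mm). Builds four-aspect mean-profile distance matrices and
    per-aspect Spearman-correlation-derived proximities, fits a common
    configuration by multi-source metric multidimensional scaling (SMACOF
    majorization minimizing normalized raw stress, PROXSCAL-style), and
    analyses the fitted space: scree-based dimensionality selection, frontier
    emotions, central-area occupancy, two-dimensional projections, Procrustes
    alignment and distance-matrix (Mantel) correlation. Includes a seeded
    truncated-normal rating simulator with optional planted low-dimensional
    structure, the published summary tables as plain-text fixtures, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
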