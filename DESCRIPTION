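Package: biofilmspat
Title: Spatial Point-Process Analysis of Mineral-Hosted Biofilm Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how microbial cell distributions on rock
    surfaces depend on underlying element (mineral) distributions mapped by
    SEM/XEDS. Provides tile stitching of element-map rasters into panoramic
    observation windows, cell and fungal feature morphology metrics
    (area, perimeter, circularity) with filament/rod/cocci classification,
    2D kernel-density hotspot surfaces and contours, inhomogeneous Poisson
    point-process models with log-linear element covariates fitted by
    Berman-Turner quadrature, nested-model likelihood-ratio tests with
    exhaustive covariate-subset search, inhomogeneous Ripley K / Besag L
    functions with Monte-Carlo simulation envelopes, community statistics
    (taxa filtering, taxa-chemistry correlation, Bray-Curtis, SIMPER), and a
    seeded synthetic-data generator of grain scenes, cell patterns, feature
    masks and community tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    EBImage,
    jsonlite,
    tiff,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
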