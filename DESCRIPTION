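Package: habcurve
Title: Evolving-Curve Segmentation and Spectral Characterization of
    Vegetation Habitats in Multiband Rasters
Version: 0.1.0
Authors@R:
    person("habcurve", "developers", email = "habcurve@example.org",
           role = c("aut", "cre"))
Description: Tools for delineating vegetation habitat patches in multiband
    satellite-style rasters with Lagrangian evolving planar curves
    (automatic closed-curve growth from seed points and semiautomatic
    open-curve fitting between anchors, driven by homogeneity, edge and
    curvature forces), for characterizing segments by per-band zonal
    statistics and the Relative High Laplacian (RHL) structural
    classifier, for validating segmentations against GPS ground-truth
    tracks with maximal and mean Hausdorff distances, and for testing
    multivariate habitat differentiation with a permutation-based
    PERMANOVA. Includes a seeded synthetic-scene generator that emulates
    habitat patches with per-band spectral distributions,
    natural-vs-plantation canopy texture, and GPS-like boundary tracks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
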