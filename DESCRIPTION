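Package: villimorph
Title: 3D Morphometry of Intestinal Villi from Confocal Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Instance segmentation and physical morphometry of intestinal
    villi in 3D fluorescence confocal stacks with anisotropic voxel spacing.
    Implements a whole-mount quantification pipeline for villus length,
    volume and surface area: sparse manual crypt annotations interpolated to
    a 3D crypt mask, crypt removal, iterative erosion plus
    Laplacian-of-Gaussian seeding, marker-controlled regrowth of villus
    instances, and geodesic distance-map length measurement together with
    Crofton and mesh surface-area estimators. Includes a synthetic
    two-channel mucosa phantom generator with analytic per-villus ground
    truth (capsule geometry with optional elliptical flattening), auxiliary
    measurements (crypt depth, villus/crypt ratio, EdU migration distance,
    organoid cross-section area), and two-level cohort summaries with Welch
    t-tests and one-way ANOVA with Tukey post hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
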