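Package: standweave
Title: Stand Structural Complexity and Biodiversity Effects in Tree
    Diversity Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional structural
    complexity of planted tree communities from terrestrial laser
    scanning point clouds and linking it to wood productivity and net
    biodiversity effects. Implements voxel-based effective number of
    layers (inverse Simpson over 25 cm height slices), mean fractal
    dimension of azimuthal cross-section polygons, and the stand
    structural complexity index (SSCI); annual wood productivity from
    two-census stem diameters and heights; additive partitioning of
    overyielding into complementarity and selection effects; the net
    biodiversity effect on structural complexity (delta-SSCI);
    community-weighted mean and functional dispersion of shade
    tolerance; a ground-light interception proxy; and a synthetic-data
    generator emulating a two-block tree diversity experiment (10
    species, two mycorrhizal types, richness 1/2/4, 80 plots of 140
    trees) so the whole chain is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
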