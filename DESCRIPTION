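Package: voxcoloc
Title: Voxel-Based Colocalization Analysis for Multi-Channel Confocal Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies colocalization between fluorescence channels of 3D
    confocal z-stacks. Reads multi-channel grayscale TIFF stacks (8-, 16- or
    32-bit, up to 15 channels), applies per-channel dual (lower/upper)
    intensity thresholds and an optional axis-aligned region-of-interest box,
    and computes Pearson's correlation coefficient for every selected channel
    pair together with global and per-channel intersection coefficients for
    two or three channels via the inclusion-exclusion principle. Produces
    unweighted Venn diagrams of overlap volume percentages,
    background-excluded 2D intensity histograms (fluorograms) as static
    images and standalone interactive HTML, and a results workbook with a CSV
    twin. Includes a synthetic-stack generator with analytically known
    channel masks and overlap volumes for validation, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
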