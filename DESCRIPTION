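Package: nfertgrid
Title: Reconstruction of Crop-Specific Nitrogen Fertilization Grids from
    National Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs long-term crop-specific nitrogen (N) fertilization
    grids -- application rate by fertilizer class (synthetic N, manure, crop
    residues), 13-way fertilizer-type shares, and surface/deep placement
    fractions -- by allocating national statistics onto an administrative
    (country/county) and raster scaffold. Implements dasymetric downscaling of
    harvested area with political-disintegration handling, constant-ratio rate
    scaling with crop-group calibration against fertilizer-use-by-crop surveys,
    bootstrap-EM multivariate-normal multiple imputation for fertilizer-type
    consumption panels, logit-ranked no-till downscaling for placement, and
    Monte Carlo uncertainty envelopes. Ships a self-consistent synthetic world
    generator with known ground truth so the whole pipeline is testable
    offline, and writes the per-crop HDF5 product layout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
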