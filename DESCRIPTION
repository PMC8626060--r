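Package: leafspec
Title: Individual-Leaf Hyperspectral Analysis of Crop Nitrogen Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing close-range hyperspectral images of single
    cereal organs (spike, flag leaf, second uppermost leaf) acquired against a
    black background. Reads and writes ENVI-format cubes, converts raw counts
    to reflectance with white/dark references, masks the organ and partitions
    it into five equal-area regions along its principal axis (apex, distal,
    central, proximal, base), computes vegetation indices (NDVI, MRE-NDVI,
    GNDVI, PSSRc) from region-mean spectra, and ranks acquisition conditions
    (organ, leaf region, shooting angle) by how well each index tracks a
    nitrogen fertilization gradient, using one-way ANOVA, Duncan's multiple
    range test and least-squares coefficients of determination. A synthetic
    data module simulates cubes and growth records with the regime structure
    of a six-level nitrogen trial so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
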