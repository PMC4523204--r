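Package: lamellaR
Title: Quantitative Image Analysis of T Cell:APC Immunological-Synapse Conjugates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for fluorescence microscopy of T cell:antigen-
    presenting-cell conjugates. Classifies sensor accumulation at the cell-cell
    interface into six mutually exclusive spatiotemporal patterns (central,
    invagination, diffuse, lamellum, peripheral, asymmetric), quantifies
    interface undulation (arc/chord ratio, tight-contact length), scores
    elongated actin structures by full-width-half-maximum line scans, computes
    depth-intensity profiles, Pearson and Manders colocalization, 3D cluster
    detection with interface-distance assignment, and single-exponential FRAP
    recovery kinetics. Ships seed-deterministic synthetic-data generators that
    emulate the imaging geometries with machine-readable ground truth, so every
    measurement can be validated against known truth.
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
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
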