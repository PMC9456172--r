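Package: focimetry
Title: Image Cytometry of DNA-Damage Foci, Cell-Cycle Kinetics and SMLM Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated-microscopy image-cytometry toolkit for DNA-damage-response
    studies. Segments nuclei on the DNA counterstain and sub-nuclear foci (gammaH2A.X,
    53BP1, PLA spots) inside them, builds per-cell feature tables with flow-cytometry-style
    logical gating, classifies DNA x EdU content into the six pulse-chase populations and
    estimates cell-cycle phase durations from chase time courses, associates proximity
    ligation assay spots with damage foci by distance, converts image coordinates to
    microscope stage positions for relocalization, and analyses single-molecule
    localization data by Gaussian rendering, image cross-correlation spectroscopy
    colocalization and object-based spot-in-focus counting. Ships ground-truthed synthetic
    generators (microscopy scenes, pulse-chase populations, PLA scenes, two-channel
    localization patterns) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
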