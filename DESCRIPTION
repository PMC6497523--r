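Package: nucmorph
Title: Nuclear Morphometry from Windowed Angle Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-throughput morphometric analysis of asymmetric cell nuclei
    (e.g. the falciform sperm heads of rodents) from fluorescence microscope
    images. Detects nuclei in grayscale TIFF images, encodes each outline as
    a windowed interior-angle profile measured at every perimeter point (a
    dense variant of the Zahn-Roskies shape transform), aligns profiles
    across a population, discovers landmarks from the median profile,
    computes a full set of size and shape parameters including a per-nucleus
    shape-variability score, builds consensus outlines, and separates
    morphological sub-populations by hierarchical clustering. Includes a
    synthetic-shape generator that renders parametric nuclei with analytic
    ground truth so the whole pipeline can be validated without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite,
    yaml,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
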