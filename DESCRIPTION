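Package: macromigr
Title: Quantitative Analysis of Macrophage Migration on Extracellular Matrix
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify macrophage migration phenotypes from time-lapse
    fluorescence microscopy: Laplacian-of-Gaussian spot detection and
    linear-assignment (LAP) track linking with gap closing, velocity and
    directness (persistence) metrics, circularity morphodynamics with
    slingshot-event detection, confocal ventral-fraction quantification,
    adhesion-assay ratios, densitometry helpers, superplot summaries and the
    associated non-parametric statistics. Includes a synthetic-data generator
    (persistent random walks in two migration modes, rendered movies,
    z-stacks, adhesion fields) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    igraph,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
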