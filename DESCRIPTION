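Package: mechanophen
Title: Mechanophenotyping of Tumor Cells: Morphometry, Migration, Stiffness
    and Focal Adhesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a mechanophenotyping
    quantification pipeline for organotropic breast-tumor clones: particle-based
    cell and bead morphometry (circularity, inverse aspect ratio, solidity,
    equivalent diameter) with ImageJ-style particle filters; time-averaged
    mean-squared-displacement analysis and persistent-random-walk fitting of
    cell trajectories (diffusion coefficient and persistence time); Hertz-model
    fitting of AFM force curves and force-map aggregation to per-cell Young's
    moduli; focal-adhesion segmentation and density scoring from two-channel
    immunofluorescence images; and the accompanying statistical battery
    (D'Agostino-Pearson normality, Kruskal-Wallis with Dunn's post hoc, ANOVA
    fallback, ROUT outlier flagging). Every input class is backed by a
    synthetic-data generator with exact ground truth, so the full pipeline is
    exercised against known answers without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
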