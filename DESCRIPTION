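Package: cyclemark
Title: Cell-Cycle Staging and Histone-Mark Inheritance Analysis for
    Reprogramming Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how histone modifications are diluted at DNA
    replication and restored through the cell cycle, and how cell-cycle
    remodelling interacts with somatic-cell reprogramming. Implements a
    dilution-restoration kinetic model of mark inheritance with a matched
    population simulator and microscopy-image renderer; an image-based
    cell-cycle staging pipeline (illumination correction, rolling-ball
    background subtraction, nucleus segmentation, one-dimensional ordering,
    six-stage assignment, and DNA-normalized mark profiles with AUC
    summaries); reprogramming-barrier gene classification from four-state
    expression; transcription-factor target-activity scoring along
    pseudotime; dynamic-time-warping comparison of expression trajectories;
    propidium-iodide histogram deconvolution with doubling-time and absolute
    phase-duration estimation; and colony-count scoring of siRNA screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
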