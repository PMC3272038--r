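Package: alemeta
Title: Activation Likelihood Estimation Meta-Analysis of Neuroimaging
    Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coordinate-based meta-analysis of neuroimaging activation foci
    using activation likelihood estimation (ALE). Reported peak coordinates
    are modelled as centres of three-dimensional Gaussian spatial-uncertainty
    distributions whose width shrinks with the number of scanned subjects;
    per-experiment modelled activation (MA) maps are combined into voxel-wise
    ALE scores, tested against a random-spatial-association null with
    cluster-level family-wise error correction, and compared across
    meta-analyses by minimum-statistic conjunction. Includes a
    GingerALE-style foci text reader/writer, Talairach/MNI affine coordinate
    conversion, cluster tables with optional atlas labels, intersection with
    external thresholded statistical maps, and a synthetic foci generator
    with planted convergence centres for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
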