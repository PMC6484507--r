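Package: ohcsync
Title: Spontaneous Outer Hair Cell Calcium Activity and Intercellular
    Wave Synchronization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for two-photon calcium-imaging
    recordings of the developing cochlea: translation registration and
    ROI-based dF/F0 trace extraction from time-lapse movies, a six-step
    activity classifier with nonnegative AR(1) spike deconvolution and a
    Welch noise-floor estimate, automated segmentation of intercellular
    calcium waves in the greater epithelial ridge with longitudinal
    extension measurement, and windowed Fisher-z-averaged Spearman
    synchronization statistics with regression of synchronization against
    wave extension. A seedable synthetic-recording generator with full
    ground truth makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    matrixStats
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
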