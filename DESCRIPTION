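Package: echotex
Title: Echotexture Analysis of Greyscale Muscle Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative echotexture analysis of B-mode muscle ultrasound
    images. Extracts 21 first-order, grey-level co-occurrence matrix (GLCM)
    and grey-level run length matrix (GLRLM) features from rectangular
    regions of interest, screens features for informativeness by a
    two-rater extreme-image agreement criterion, relates echovariation (the
    coefficient of variation of pixel intensity) to ordinal muscle
    impairment grades, and fits a double-exponential-plus-offset model to
    the sorted echovariation distribution. Includes a seeded generator of
    graded synthetic speckle-image cohorts so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
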