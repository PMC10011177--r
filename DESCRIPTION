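Package: wavsal
Title: Wavelet-Based Bottom-Up Visual Saliency Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up visual saliency model built on multi-feature
    center-surround contrast over a Symlet-4 wavelet approximation pyramid.
    An RGB image is decomposed into low-level channels (intensity, CIELab
    color opponency, Gabor orientation energy) and medium-level channels
    (orientation filtering of the opponency channels), center-surround
    difference maps are computed between pyramid scales under configurable
    4/6/10-map schemes, scales are fused with contrast-sensitivity-function
    weighting (global and local), and features are integrated into a final
    saliency map by one of four methods. Includes AUC-Borji and shuffled-AUC
    fixation metrics, a synthetic pop-out stimulus and fixation generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    tools,
    utils,
    png,
    jpeg,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
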