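Package: spotseg
Title: Unsupervised Segmentation and Quantification of Two-Channel Microarray Spots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised image analysis pipeline for two-channel (Cy3/Cy5)
    cDNA microarray scans. Grid alignment is driven by a one-dimensional
    shock-filter partial differential equation that sharpens averaged
    luminance profiles into piecewise-constant plateaus, placing borderlines
    at inflection points between rows and columns of spots. Per-spot borders
    are refined from slice profiles, gaps are filled by autocorrelation-based
    periodic continuation, and each spot is initialised with a triplet of
    adapted ellipses (foreground, exclusion zone, background) before a local
    deterministic 2-means clustering of pixel intensities in both channels
    recovers irregular contours and inner holes. Background-corrected median
    intensities, R/G ratios, pixelwise regression ratios with coefficients of
    determination, lowess normalisation and up-regulation calls are computed
    per spot. A synthetic slide simulator with full ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
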