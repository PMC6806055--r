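Package: thermoface
Title: Automatic Forehead Segmentation and Temperature Extraction from
    Thermographic Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments the forehead region in single-camera thermal-infrared
    frames and extracts its mean temperature without user interaction beyond a
    glasses flag.  The pipeline converts the raw temperature matrix to 8-bit
    grayscale, removes the background with an Otsu threshold and a contrast
    stretch, extracts the head contour by binary erosion and XOR, fits a
    direct least-squares ellipse to the contour, locates the eyes (or glasses
    lenses) in the upper half-ellipse with a two-cluster K-means seeded from
    the ellipse geometry, and cuts the forehead above a line through the
    shifted eye midpoint.  A synthetic thermal-phantom generator with analytic
    ground truth and a Jaccard (IoU) evaluation harness make every stage
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    png,
    tiff,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
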