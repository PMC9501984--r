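Package: exhist
Title: Exact Histogram Equalization and Specification by Local-Contrast
    Pixel Ordering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact histogram equalization and specification of 8-bit
    grayscale and RGB images. Pixels sharing a quantized value are ordered
    strictly by their local contrast, the signed deviation from a
    non-truncated (all-pixel) Gaussian-weighted mean computed by separable
    matrix products; the resulting total order is voted into an arbitrary
    target histogram so that the output histogram equals the target
    bin-for-bin. Includes the Nikolova-Steidl fully smoothed l1-TV
    fixed-point ordering as a baseline method, conventional (inexact)
    equalization and specification, a hue-preserving unified-channel color
    extension, target-histogram construction, evaluation metrics (RMSE,
    circular hue RMSE, difference images, profiles), synthetic test-image
    generators, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
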