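Package: kymoalign
Title: Weighted-Path Alignment of Nanochannel Optical DNA Mapping Kymographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Straightens kymographs from nanochannel-based optical DNA mapping
    experiments by detecting the most pronounced bright or dark intensity ridge
    as a continuity-constrained shortest path through a Laplacian-of-Gaussian
    cost landscape, aligning it to its mean position by per-row cubic-spline
    resampling, and recursing over the flanking sub-images. Includes barcode
    quality metrics (column-wise variance of the time trace and a
    self-information score computed from peak/valley contrasts) and a synthetic
    kymograph simulator with known ground-truth distortions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
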