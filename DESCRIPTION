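Package: dermoseg
Title: Dermoscopic Skin-Lesion Segmentation by Bit-Plane Slicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the border of a pigmented skin lesion in a dermoscopic
    image using most-significant-bit-plane slicing of the RGB channels, a 7x7
    Hanning-window low-pass filter with one-bit re-quantization, and summation
    of the three filtered planes into a four-level segmentation map from which
    a lesion mask, an ordered border contour and per-region color histograms
    are extracted. Includes pixel-level accuracy evaluation against expert
    ground-truth masks, a synthetic dermoscopy fixture generator with exact
    ground truth, and a command-line interface for segment/evaluate/synth
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jpeg,
    jsonlite,
    png,
    purrr,
    rlang,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
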