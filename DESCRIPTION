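Package: graftunet
Title: Graft-U-Net Encoder-Decoder Segmentation of Colonoscopy Polyps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end implementation of the Graft-U-Net approach to
    binary polyp segmentation on colonoscopy frames. Provides
    contrast-limited adaptive histogram equalization (CLAHE) preprocessing
    with the Reza clip-limit formula, a five-stage graft-block
    encoder/decoder network with skip connections built and trained
    entirely on the CPU, a symbolic layer-shape trace checked against the
    published layer table, confusion-count segmentation metrics (Dice,
    IoU, recall, precision, F2, accuracy), Kvasir-SEG-style paired-folder
    dataset handling, and a seeded generator of synthetic colonoscopy-like
    frames with pixel-exact masks so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
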