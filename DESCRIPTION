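Package: dropfreq
Title: Droplet Generation Frequency Monitoring from High-Speed Microscopy Video
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Monitors dynamic droplet-generation processes in microfluidic
    devices from high-speed microscopy video. Each video frame is flattened to
    a grayscale vector and compared with a designated reference frame by
    cosine similarity; the resulting similarity vector oscillates at the
    droplet generation rate, and its cyclic auto-spectrum (FFT periodogram)
    yields the generation frequency's mean and coefficient of variation.
    Supports batch estimation on whole clips, simultaneous multi-channel
    estimation via spectral peak separation with harmonic grouping, windowed
    online monitoring of long processes, and FIFO ring-buffer streaming with
    constant per-frame cost. Includes a synthetic droplet-video simulator with
    exact ground truth for validation, lossless AVI and PNG/TIFF frame-stack
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
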