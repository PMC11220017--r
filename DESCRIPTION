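Package: ewsfd
Title: Entropy-Weighted Spectral Fractal Dimension for Low-Light Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes Shannon entropy, spectral box-counting fractal
    dimensions (equal- and different-spectral-resolution forms) and the
    entropy-weighted spectral fractal dimension (EW-SFD) of 1-16 bit
    grayscale or multi-band image data, together with a time-lapse
    analysis pipeline for ultraweak photon emission recordings:
    multi-page TIFF stack input/output, region-of-interest extraction,
    pixel-wise dark and background correction, integration-time
    rebinning, effective data-depth estimation and per-frame metric
    time series. Includes a seeded Poisson synthetic-stack generator
    emulating live, degenerating and background emission scenarios, and
    a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
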