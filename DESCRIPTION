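Package: ppgwave
Title: Wavelet Baseline Correction and Modulus-Maximum Peak Detection for
    Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for photoplethysmography (PPG) waveform analysis: suppression
    of baseline drift and low-frequency motion artifacts by multiresolution
    analysis with the sym8 wavelet, automatic systolic peak detection from the
    modulus maxima of an undecimated quadratic-spline wavelet transform,
    detector evaluation against reference beat annotations, pulse-oximetry
    SpO2 estimation by the ratio-of-ratios method, and a seeded synthetic PPG
    generator with ground-truth beat positions for validation. Includes a
    command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
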