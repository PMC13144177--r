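Package: lifhsi
Title: Laser-Induced Fluorescence Hyperspectral Contamination Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pixel-wise detection and mapping of fluorescent organic
    contaminants (such as sunscreen UV filters) on crystalline food
    matrices from laser-induced fluorescence hyperspectral image cubes.
    Provides ENVI-format cube input/output, two-point radiometric
    calibration against white and dark references, a five-step spectral
    preprocessing pipeline (laser-band removal, percentile baseline
    subtraction, negative clipping, area normalization, Savitzky-Golay
    smoothing), sparse principal component analysis with an adaptive
    relative soft-threshold and Hotelling deflation, RBF support vector
    machine classification of pixel spectra, ground-truth based spatial
    evaluation (confusion counts, accuracy/precision/recall/F1, error
    maps), and a synthetic phantom-scene generator for validation
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    pracma,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
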