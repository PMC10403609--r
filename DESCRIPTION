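Package: CaSparkML
Title: Machine Learning on Composite Calcium-Spark Waveform Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for screening treatment effects on ATP-triggered
    intracellular calcium sparks in neural stem cell cultures. Extracts
    per-cell calcium waveforms from time-lapse fluorescence movies via
    hexagonal ROI segmentation, Gaussian baseline-noise estimation and
    threshold spike detection; rasterizes waveforms into fixed-axis
    grayscale images; builds 3 x 3 composite training images of nine
    same-group waveforms; trains and evaluates a local image classifier
    with precision/recall reporting and voting-based segregation of
    untrained substances; and provides the classical statistics (unpaired
    Student's t tests on spike frequency and dynamic range, responder
    fractions) that the image classifier is benchmarked against. A
    seed-deterministic simulator of calcium traces and movies provides a
    fully synthetic two-group benchmark with matched classical marginals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    digest,
    jsonlite,
    yaml,
    jpeg,
    png,
    tiff,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'compositor.R'
    'extract.R'
    'io.R'
    'learn.R'
    'pipeline.R'
    'render.R'
    'simulate.R'
    'stats.R'
    'utils.R'
RoxygenNote: 7.3.3
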