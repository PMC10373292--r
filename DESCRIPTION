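Package: cardiowave
Title: Optical Mapping, Phase Singularity and Field-Potential Analysis for
    Cardiomyocyte Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction for cardiac optical-mapping movies and
    multi-electrode-array (MEA) electrograms from cultured cardiomyocyte
    monolayers. Implements the optical conditioning chain (sliding-window
    normalization, masked Gaussian smoothing, zero-phase Butterworth
    band-pass, Hanning edge tapering, truncated Fourier re-synthesis),
    Hilbert-transform phase mapping with double-ring phase-singularity
    detection and greedy rotor tracking, beat segmentation with APD30/APD90
    quantification, and MEA metrics (beat period, Fridericia-corrected field
    potential duration, spike amplitude, plane-fit conduction velocity,
    vehicle-adjusted drug deltas). Ships a two-variable Aliev-Panfilov
    excitable-medium simulator with an independent isopotential tip oracle
    so every analysis stage is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
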