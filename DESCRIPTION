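Package: nirphasor
Title: Spectral-Phasor Hyperspectral NIR Imaging Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and analysis toolkit for tunable spectral-phasor
    hyperspectral imaging in the near infrared (900-1600 nm). Provides an
    optical forward model of a liquid-crystal variable retarder between
    parallel polarizers that approximates sine-, cosine- and total-transmission
    filters over an adjustable spectral window; retardance calibration by
    correlation against ideal targets; the three-frame spectral phasor
    transform with its exact-Fourier oracle; an EMVA-1288 camera noise model
    for InGaAs detectors predicting phasor uncertainty versus photon flux;
    synthetic generators for narrow-band NIR emission spectra, reflectance
    spectra with a 1450 nm water absorption band, spatial scenes and
    water-uptake time series; and downstream analyses including two-endmember
    phasor unmixing, polygon gating, angular colour coding, spatial
    G/S correction fields and a sliding-window rate-of-change pipeline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
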