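Package: ftirpls
Title: Chemometric Model Selection for FT-IR Metabolic Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end chemometric workflow for discriminating sample
    classes (such as cultivation age or plant part) from Fourier-transform
    infrared (FT-IR) spectra. Provides spectral preprocessing (transmittance
    to absorbance conversion, Savitzky-Golay derivatives, water-vapor and
    CO2 region removal, area / min-max / vector normalization), NIPALS
    partial least squares for PLS-DA and PLSR with cross-validated Q2Y,
    variable influence on projection (VIP) selection, permutation-test
    model validation with R2Y/Q2Y intercepts, and a two-stage model
    selection procedure that screens preprocessing configurations and then
    sweeps VIP cutoffs to minimize prediction error on a held-out
    analytical replicate. Includes a synthetic FT-IR spectrum generator
    with class-dependent absorption bands for testing the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
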