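Package: spiralT1
Title: Golden-Angle Spiral Inversion-Recovery Blood T1 Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, reconstruction and quantification pipeline for
    ultrafast blood T1 measurement with a single-shot golden-angle rotated
    variable-density spiral acquisition. Provides a digital inflow vessel
    phantom with a Look-Locker inversion-recovery signal model, Bloch-level
    simulation of the adiabatic hyperbolic-secant inversion pulse and the
    WET pre-saturation train, non-Cartesian SENSE reconstruction with
    temporal total-variation regularization solved by nonlinear conjugate
    gradient (including sign-inverted periodic frame padding and
    frequency-segmented off-resonance deblurring), and downstream analysis:
    rigid frame registration, FWHM vessel segmentation, three-parameter
    inversion-recovery T1 fitting with confidence-interval based exclusion,
    and method-comparison statistics (linear regression and Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    minpack.lm,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
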