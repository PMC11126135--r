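Package: ivimfield
Title: Field-Strength Dependence of Intravoxel Incoherent Motion Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the magnetic-field-strength dependence of
    intravoxel incoherent motion (IVIM) parameters in skeletal muscle.
    Implements the segmented IVIM fit of ROI-mean diffusion-weighted signal
    curves, a three-compartment (muscle, arterial blood, venous blood)
    relaxation-weighting model that maps measured perfusion fractions to
    proton-density-weighted perfusion fractions across field strengths,
    quadratic interpolation of blood transverse relaxation rates, Rayleigh
    noise-floor SNR estimators, a seeded Rician-noise study simulator with
    known ground truth, and normality-gated paired comparisons.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
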