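Package: megsource
Title: MEG Source Reconstruction, Time-Frequency Beamforming, Connectivity
    and Nonparametric Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable sensor-to-source analysis pipeline for
    magnetoencephalography (MEG). Implements spherical-conductor forward
    modelling (single-sphere and per-channel multisphere head models),
    a menu of inverse solutions (LCMV vector/scalar/eigenspace
    beamformers, minimum-norm estimation with dSPM and sLORETA
    standardisation, and the Champagne empirical-Bayes sparse solver),
    a three-step time-frequency beamformer producing pseudo-F maps of
    induced oscillatory power, source-space functional connectivity
    (imaginary coherence, magnitude-squared coherence, phase lag index,
    amplitude envelope correlation, general lagged coherence), dual
    signal subspace projection (DSSP) interference suppression, and
    voxelwise nonparametric group statistics based on sign-flip
    permutations of a smoothed-variance pseudo-t with FWER, FDR and
    cluster corrections. A built-in dipole simulator generates epoched
    recordings and multi-subject group data with known ground truth.
    Volumetric results export to NIfTI-1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
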