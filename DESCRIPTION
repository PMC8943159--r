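Package: lagbold
Title: Spherical-Laguerre HRF Estimation and Longitudinal Mixed-Effects
    Mapping for Block-Design fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing two-condition block-design BOLD fMRI with
    condition-specific hemodynamic response functions (HRFs). HRFs are
    estimated by ordinary least squares on an orthonormal spherical-Laguerre
    basis expansion, with cross-validated grid search over the basis decay
    and delay parameters and BIC model-order selection. Downstream stages
    provide condition-specific-HRF activation GLMs, generalized
    psychophysiological interaction (gPPI) seed connectivity, lightweight
    preprocessing (confound expansion, DVARS scrubbing, anisotropic Gaussian
    smoothing), and voxel-wise longitudinal linear mixed-effects mapping
    with sign-flip cluster-extent FWER control, FDR adjustment, simple
    slopes and floodlight (Johnson-Neyman) moderation analysis. A synthetic
    data module generates block designs, ground-truth HRFs, noisy 4D BOLD
    runs and longitudinal cohorts with planted effects so the whole chain
    is testable against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
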