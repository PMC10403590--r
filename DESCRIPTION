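Package: obscope
Title: Optoacoustic Blood-Stethoscope Imaging and Vascular Biomarker Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational stack for a flexible wearable optoacoustic blood
    'stethoscope': Fourier-domain (phase-shift, non-uniform-FFT) volumetric
    image reconstruction for layered media with a delay-and-sum baseline and
    an independent forward simulator; Monte Carlo photon transport for
    comparing skin-illumination geometries; receive-field modelling of
    rectangular piezoelectric elements and array field-of-view statistics;
    and downstream cardiovascular biomarker estimation (oxygen-saturation
    calibration, exogenous-agent decay kinetics, venous compliance, and
    flow-mediated dilation) from optoacoustic amplitude trend series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    utils,
    Rcpp,
    stats,
    tiff,
    RNifti,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
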