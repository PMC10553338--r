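Package: pcctcardiac
Title: Photon-Counting Micro-CT Cardiac Phenotyping at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for spectral photon-counting
    micro-CT (PCCT) cardiac phenotyping in the mouse. Provides a dynamic
    spectral phantom with a beating, iodine-enhanced left ventricle and a
    calcium detectability phantom; an energy-binned photon-counting
    acquisition model with Poisson noise; retrospective intrinsic cardiac
    gating from the projection data alone; filtered backprojection and
    multi-channel split-Bregman iterative reconstruction with temporal
    bilateral filtration and rank-sparse energy regularization; sensitivity
    matrix calibration and K-edge material decomposition with orthogonal
    subspace projection; contrast-to-noise detectability analysis under the
    Rose criterion; a trainable U-Net left-ventricle segmenter; and cardiac
    function statistics (stroke volume, ejection fraction, cardiac output and
    index) with factorial linear models, Tukey post hocs and effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    signal,
    emmeans,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
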