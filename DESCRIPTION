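Package: cellmech
Title: Nanomechanical Characterization of Single Cells from AFM Force Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of atomic force microscopy (AFM)
    microindentation experiments on living cells. Force-displacement curves
    are baseline-corrected, the tip-sample contact point is detected by a
    piecewise model search, and the apparent Young's modulus is estimated by
    Hertz spherical-contact fitting within a bounded indentation window.
    Per-cell stiffness distributions are deconvolved into one- or
    two-component Gaussian subpopulations with a BIC-guarded EM fit, yielding
    a unimodal/bimodal heterogeneity label. Companion modules fit
    four-parameter logistic dose-response curves (IC50), quantify
    treatment-induced stiffness change (CV%), classify cell morphology from
    binary masks (circularity, aspect ratio), extract 10-bin centroid
    crossline fluorescence profiles and uptake ratios, and run the
    association layer (regression, group comparisons, median dichotomization,
    housekeeping-normalized differential expression). A full synthetic-data
    generator provides Hertzian indentation curves with instrument noise,
    mixture stiffness populations, viability tables, elliptical cell images
    and expression matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    tiff,
    EBImage,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
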