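Package: orgredox
Title: Wide-Field Redox Imaging Analysis for Patient-Derived Cancer Organoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated image-analysis and statistics framework for
    wide-field one-photon redox imaging of patient-derived cancer organoids.
    Registers two-channel NAD(P)H/FAD fluorescence time series, computes
    per-pixel optical redox ratio (ORR) images, segments organoids with a
    12-step edge-enhancement algorithm, links individual organoids across a
    48-hour treatment course with linear-assignment tracking and gap closing,
    quantifies 24 metabolic and morphological variables per organoid and
    time point, and analyses the resulting longitudinal data with
    random-intercept mixed-effect models (AR(1) residual correlation),
    estimated-marginal-means Tukey contrasts, and a pretreatment-anchored
    principal component analysis. A synthetic phantom generator with full
    ground truth makes every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    nlme,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
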