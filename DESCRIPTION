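Package: striatr
Title: Automated Striatal-to-Reference Ratio Quantification for Dopamine
    Transporter SPECT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated quantification of striatal dopamine-transporter
    uptake from reconstructed [99mTc]-TRODAT-like SPECT volumes. Builds a
    normal template from control scans, defines template-space striatal and
    cortical-reference volumes of interest (VOIs), spatially normalizes each
    subject with an affine plus low-frequency cosine-basis deformation,
    inverts the deformation to carry the VOIs back onto the untouched native
    image, and computes the striatal-to-reference ratio (SRR). Includes a
    digital brain phantom and cohort simulator, ROC-based diagnostic
    evaluation with Youden-optimal cutoffs and McNemar comparison of paired
    pipelines, and a quadratic clinical-duration model with preclinical
    extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    pROC,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
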