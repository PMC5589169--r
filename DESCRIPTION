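Package: rbcfluidity
Title: Membrane Fluidity Mapping and Phase-Separation Pattern Classification for Red Blood Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying red-blood-cell plasma-membrane fluidity from
    two-channel Laurdan fluorescence images. Computes per-pixel generalized
    polarization (GP) maps with background subtraction and debris removal,
    extracts first-order, gray-level co-occurrence and rotation-invariant
    co-occurrence local binary pattern texture descriptors per emission
    channel, and classifies patients into healthy / diabetic / diabetic-with-
    complications groups with a decision-support system (per-channel PCA +
    support vector machine pipelines fused by weighted voting) evaluated
    leave-one-person-out, alongside Gaussian Bayes baselines on scalar
    biomarkers. Includes a seeded synthetic-cohort simulator (annular cell
    geometry, class-dependent fluid-domain nucleation, Poisson photon noise,
    clinical covariates) so the whole pipeline is testable without patient
    data, and the descriptive cohort statistics (group tests, normalization
    to controls, coefficients of variation, regressions against disease
    duration, lipids and insulin dose).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    png,
    jsonlite,
    yaml,
    e1071,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
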