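Package: pabifurc
Title: Pulmonary Artery Bifurcation Morphometry and Short-Term Risk Scoring
Version: 0.1.0
Authors@R:
    person("pabifurc", "maintainers", email = "maintainers@pabifurc.invalid",
           role = c("aut", "cre"))
Description: Geometric morphometry of the main pulmonary artery (MPA)
    bifurcation on triangulated vessel surfaces, and construction and
    evaluation of a sparse linear risk score for short-term adverse events
    in non-high-risk acute pulmonary embolism. Includes a parametric
    bifurcation mesh generator with analytic ground truth, centerline
    extraction and perpendicular cross-section metrology (cross-sectional
    area, hydraulic and maximal diameter, bifurcation area/angle/volume),
    LASSO-logistic score fitting with 1-SE lambda selection, ROC/DeLong,
    cross-validated precision-recall and decision-curve evaluation, a
    synthetic cohort simulator, and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
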