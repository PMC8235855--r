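Package: longsad
Title: Structured Antedependence Models for Longitudinal Residual Feed Intake
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate structured-antedependence (SAD) mixed models for
    longitudinal feed intake and production traits in pedigreed populations.
    Builds numerator relationship matrices, assembles SAD covariance functions
    (within-trait antedependence and cross-antedependence of feed intake on
    production traits), estimates parameters by REML in an animal model,
    derives residual feed intake criteria that are genetically independent of
    production traits at every time point, and summarises breeding-value
    trajectories by eigendecomposition for selection. Includes a synthetic
    data generator emulating a pig feed-efficiency design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
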