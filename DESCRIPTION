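Package: connsweep
Title: Threshold-Swept Structural Connectome Association Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds weighted structural brain networks from per-participant
    streamline-count and radial-diffusivity connectivity matrices, sweeps
    streamline-count thresholds calibrated to target network densities,
    computes subnetwork graph metrics (node degree, nodal strength, weighted
    clustering coefficient), and relates them to a trait score (schizotypy,
    measured by the Schizotypal Personality Questionnaire) via partial
    correlations correcting for age and sex, with Cook's-distance outlier
    exclusion, Benjamini-Hochberg false-discovery-rate control, persistence
    classification across thresholds, and node-driver analysis.  A synthetic
    cohort generator with a plantable connectivity-trait effect provides
    ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
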