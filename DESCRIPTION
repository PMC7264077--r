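Package: megpls
Title: Source-Space MEG Band Power and Partial Least Squares for Preterm
    Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking frequency-specific neuromagnetic source power
    to group membership, neurocognitive outcome and thalamic structure in
    cohorts of children born very preterm. Implements relative band power
    from source-projected MEG (motion rejection, epoching, canonical band
    filtering, LCMV beamforming with a regularized covariance), mean-centered
    and behavioral Partial Least Squares with permutation tests on singular
    values and bootstrap-ratio salience maps, the thalamic-to-cortical volume
    ratio, post-hoc salience-map analyses and neonatal-predictor regressions.
    A synthetic cohort generator with recorded ground truth supports
    calibration and recovery testing of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
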