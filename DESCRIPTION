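Package: covertrace
Title: Quantitative Cover-Test Analysis of Video-Oculography Gaze Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying latent and manifest ocular deviation from
    video-oculography recordings of the cover test. A four-parameter logistic
    model is fitted to the occluded-eye deviation signal to extract the
    deviation angle, peak deviation speed, stabilization time (90% of the
    asymptotic deviation) and overshoot depth, with detection of
    rebound-saccades in tropic refixation. Includes a seedable synthetic
    trace simulator with analytic ground truth for phoric and tropic
    morphologies, degree/prism-diopter conversion, an exact permutation
    Spearman rank correlation test for small samples, cohort-level summary
    statistics, trace CSV input/output, trajectory figures, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
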