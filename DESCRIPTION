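Package: anctrends
Title: Antenatal Care Content and Timing Indicators from Survey Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation pipeline for antenatal care (ANC) content and
    timing indicators across country panels: simulation of survey
    microdata with realistic recall windows and abbreviated item sets,
    survey tabulation with design effects, meta-regression crosswalking
    of abbreviated composite definitions, three-stage spatiotemporal
    Gaussian process regression (mixed-effects prior, space-time
    residual smoothing, per-country GP conditioning), and draw-level
    post-processing (consistency raking, rescaling by ANC attendance,
    livebirth-weighted aggregation, percentile uncertainty intervals,
    outcome correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
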