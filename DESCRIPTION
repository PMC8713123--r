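Package: expowin
Title: Exposure-Window Selection for Ambient Environment and Disease Severity
Version: 0.1.0
Authors@R:
    person("Expowin", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to find which trailing moving-average window of ambient
    weather and pollution variables best associates with a dichotomized
    disease-severity outcome. Provides hourly-to-daily ingestion with quality
    control, multivariate expectation-maximization imputation with spline time
    trends, recruitment-matched trailing-average exposure matrices,
    principal-component composites for collinear variable pairs, penalized
    B-spline additive models (logistic and Gaussian) with REML-type smoothing
    parameter selection, AIC top-model-set selection with a delta-AIC-6
    threshold and the nesting rule, double-penalty term selection, a
    surrogate-prediction experiment for long-window ozone, and a synthetic-data
    generator with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
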