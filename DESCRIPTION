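Package: stridetrends
Title: Piecewise-Linear Trends and Scaling Analysis of Gait Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing stride-to-stride dynamics of treadmill
    walking. Fits explicit piecewise-linear trends to stride time, stride
    length and stride speed series with an additive MARS (multivariate
    adaptive regression splines) model, estimates scaling (Hurst) exponents
    of trends and residuals with detrended fluctuation analysis and the
    madogram estimator, characterises trend durations and slopes with
    exponential and Cauchy fits, generates fractional Brownian motion and
    coupled synthetic gait trials, builds phase-randomized surrogate series,
    and quantifies trend-based speed control via the trend speed control
    (TSC) parameter.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
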