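Package: icreach
Title: Continuous and Intermittent Optimal Control of Reaching Movements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models reaching movements of a muscle-actuated hand under
    linear-quadratic-Gaussian (LQG) control when the controller's internal
    model of the limb is inaccurate. Provides gain synthesis (algebraic and
    differential Riccati equations), closed-loop simulation of the
    observer-predictor-feedback architecture with measurement delay under
    continuous control and under periodic intermittent control with a
    system-matched hold, Sylvester-equation-based monodromy matrices that
    decide the stability of the sampled-data loop with and without delay,
    mass/damping stability-threshold scans, and dysmetria (overshoot and
    undershoot) metrics for simulated reaches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
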