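Package: gaitnorm
Title: Normative Walking Biomechanics via Function-on-Scalar Regression
Version: 0.1.0
Authors@R:
    person("gaitnorm", "developers", email = "gaitnorm@example.org",
           role = c("aut", "cre"))
Description: Fits penalized function-on-scalar regression models that predict
    normative walking biomechanics waveforms (joint angles, ground reaction
    forces, joint moments and powers over the 100-point normalised gait cycle)
    from seven scalar covariates: sex, age, walking speed, body mass, height,
    cadence and side.  Provides B-spline tensor-product smooths with
    difference penalties, REML/GCV smoothing selection, functional subject
    random intercepts, pointwise uncertainty bands, smooth-effect extraction
    at covariate quantiles, curve-level RMSE / relative RMSE / correlation
    evaluation under a participant-level train/test split, a synthetic
    lifespan gait cohort generator with known ground truth, and a command
    line interface tying the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    grDevices,
    jsonlite,
    methods,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
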