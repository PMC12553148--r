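test_that("side enters predictions as a constant offset equal to beta_side", {
  fit <- shared_fit()$fit
  prof <- list(sex = "female", age = 30, speed = 1.3, mass = 60, height = 1.65,
               cadence = 110, side = "left")
  prof_r <- prof; prof_r$side <- "right"
  d <- predict_mean(fit, prof_r)$table$mean - predict_mean(fit, prof)$table$mean
  beta_side <- fit$coef_blocks$side
  expect_equal(d, rep(beta_side, 100), tolerance = 1e-10)
})

test_that("an unpenalized fit reproduces training fitted values", {
  tr <- default_truth(sigma_eps = 0.3, sigma_b = 0)
  coh <- generate_cohort(10, seed = 19, tr)
  cfg <- small_config(include_random = FALSE, lambda = 1e-8)
  fit <- fit_fosr(coh$curves, coh$covariates, config = cfg)
  des <- assemble_design(coh$covariates, config = cfg)
  fitted <- as.numeric(des$X %*% fit$coefficients)
  rec <- coh$covariates[4, ]
  pred <- predict_mean(fit, rec)$table$mean
  expect_equal(pred, fitted[301:400], tolerance = 1e-8)
})

test_that("a noiseless saturated fit recovers the population mean curve", {
  # with zero noise and lambda -> 0 the only error left is the spline
  # approximation of the (non-spline) truth surfaces, which saturated bases
  # push well below 0.05 outcome units
  tr <- default_truth(sigma_eps = 0, sigma_b = 0)
  tr$subject_coef_sd <- 0
  coh <- generate_cohort(40, seed = 29, tr)
  cfg <- fosr_config(n_basis_t = 24, n_basis_x = 8, n_basis_tensor_t = 20,
                     include_random = FALSE, lambda = 1e-8)
  fit <- fit_fosr(coh$curves, coh$covariates, config = cfg)
  for (r in c(3, 47, 101)) {
    rec <- coh$covariates[r, ]
    pred <- predict_mean(fit, rec)$table$mean
    mu <- true_mean_curve(rec, coh$truth[[1]], include_subject = FALSE)
    expect_lt(max(abs(pred - mu)), 0.05)
  }
})

test_that("out-of-range covariates are refused with an informative message", {
  fit <- shared_fit()$fit
  prof <- list(sex = "male", age = 300, speed = 1.3, mass = 60, height = 1.65,
               cadence = 110, side = "left")
  expect_error(predict_mean(fit, prof), "age.*range|range.*age")
})

test_that("Wald bands use the Gaussian critical value", {
  fit <- shared_fit()$fit
  prof <- list(sex = "male", age = 40, speed = 1.2, mass = 70, height = 1.75,
               cadence = 105, side = "left")
  pb <- predict_band(fit, prof, level = 0.95, kind = "ci")
  tb <- pb$table
  expect_true(all(tb$lower95 <= tb$mean & tb$mean <= tb$upper95))
  expect_equal(tb$upper95 - tb$mean, 1.959964 * tb$sd, tolerance = 1e-6)
  expect_error(predict_band(fit, prof, level = 1.2), "level")
})

test_that("the population-SD band dominates the CI band", {
  fit <- shared_fit()$fit
  prof <- list(sex = "female", age = 55, speed = 1.1, mass = 65, height = 1.6,
               cadence = 100, side = "right")
  ci <- predict_band(fit, prof, kind = "ci")$table
  sd <- predict_band(fit, prof, kind = "sd")$table
  expect_true(all(sd$upper95 - sd$lower95 > ci$upper95 - ci$lower95))
  expect_true(all(sd$sd >= ci$sd))
})

test_that("confidence bands narrow as the cohort grows", {
  tr <- default_truth(sigma_eps = 0.5, sigma_b = 0.5)
  cfg <- small_config(lambda = 1)
  width_at <- function(n) {
    coh <- generate_cohort(n, seed = 71, tr)
    fit <- fit_fosr(coh$curves, coh$covariates, config = cfg)
    prof <- list(sex = "male", age = 45, speed = 1.2, mass = 70,
                 height = 1.7, cadence = 110, side = "left")
    mean(predict_band(fit, prof, kind = "ci")$table$sd)
  }
  expect_lt(width_at(100), width_at(25))
})

test_that("prediction is additive in the per-term effects", {
  fit <- shared_fit()$fit
  p1 <- list(sex = "female", age = 35, speed = 1.4, mass = 62, height = 1.66,
             cadence = 112, side = "right")
  p2 <- list(sex = "male", age = 60, speed = 1.0, mass = 80, height = 1.78,
             cadence = 98, side = "left")
  d_pred <- predict_mean(fit, p1)$table$mean - predict_mean(fit, p2)$table$mean
  d_terms <- rep(0, 100)
  for (nm in names(fit$ranges)) {
    eff <- extract_smooth_effect(fit, nm, values = c(p1[[nm]], p2[[nm]]))
    d_terms <- d_terms + eff$estimate[eff$x == p1[[nm]]] -
      eff$estimate[eff$x == p2[[nm]]]
  }
  d_terms <- d_terms + fit$coef_blocks$sex * 1 + fit$coef_blocks$side * 1
  expect_equal(d_pred, d_terms, tolerance = 1e-8)
})

test_that("covariate_quantiles follows the linear-interpolation definition", {
  expect_equal(covariate_quantiles(data.frame(x = 1:100), "x"),
               c(25.75, 50.5, 75.25))
  expect_equal(covariate_quantiles(data.frame(x = rep(7, 5)), "x"),
               c(7, 7, 7))
  expect_error(covariate_quantiles(data.frame(x = numeric(0)), "x"), "no values")
})

test_that("smooth effects are centred and refuse scalar terms", {
  sf <- shared_fit()
  fit <- sf$fit
  # mean over the training covariate values is zero at every t
  ages <- sf$cohort$covariates$age
  eff <- extract_smooth_effect(fit, "age", values = ages)
  emat <- matrix(eff$estimate, nrow = 100)  # t x training values
  expect_lt(max(abs(rowMeans(emat))), 1e-6)
  expect_true(all(eff$lower95 <= eff$estimate & eff$estimate <= eff$upper95))
  # default evaluation points are the training quantiles
  eff_q <- extract_smooth_effect(fit, "speed")
  expect_equal(unique(eff_q$x), fit$metadata$quantiles$speed)
  expect_error(extract_smooth_effect(fit, "sex"), "scalar")
  expect_error(extract_smooth_effect(fit, "bogus"), "not a fitted smooth")
})

test_that("a null speed effect stays inside three standard errors", {
  tr <- default_truth(sigma_eps = 0.5, sigma_b = 0.3)
  tr$f$speed <- function(x, t) 0 * t + 0 * x[1]
  coh <- generate_cohort(40, seed = 83, tr)
  fit <- fit_fosr(coh$curves, coh$covariates,
                  config = small_config(lambda = 1))
  eff <- extract_smooth_effect(fit, "speed")
  expect_lt(max(abs(eff$estimate)), 3 * max(eff$se))
})

test_that("fit bundles round-trip with bit-identical predictions", {
  fit <- shared_fit()$fit
  dir <- file.path(withr::local_tempdir(), "bundle")
  save_fosr_fit(fit, dir)
  fit2 <- load_fosr_fit(dir)
  prof <- list(sex = "female", age = 28, speed = 1.5, mass = 58, height = 1.62,
               cadence = 118, side = "left")
  expect_identical(predict_mean(fit2, prof)$table, predict_mean(fit, prof)$table)
  expect_identical(predict_band(fit2, prof, kind = "sd")$table,
                   predict_band(fit, prof, kind = "sd")$table)
  expect_identical(extract_smooth_effect(fit2, "age"),
                   extract_smooth_effect(fit, "age"))
})
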