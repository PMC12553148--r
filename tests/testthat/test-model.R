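test_that("assemble_design stacks one row per (observation, t) pair", {
  cov <- sample_covariates(4, seed = 2)[c(1, 5), ]
  des <- assemble_design(cov, config = small_config())
  expect_equal(nrow(des$X), 200L)
  # disjoint contiguous column ranges covering 1..p
  cols <- unname(unlist(lapply(des$blocks, `[[`, "cols")))
  expect_identical(sort(cols), seq_len(des$p))
  for (b in des$blocks) expect_identical(b$cols, seq(min(b$cols), max(b$cols)))
  # indicator coding: male = 0 / female = 1, left = 0 / right = 1
  sex_col <- des$X[, des$blocks$sex$cols]
  expect_equal(sex_col[seq(1, 200, by = 100)],
               as.numeric(cov$sex == "female"))
  side_col <- des$X[, des$blocks$side$cols]
  expect_equal(side_col[seq(1, 200, by = 100)],
               as.numeric(cov$side == "right"))
})

test_that("random-effect block can be excluded and missing fields are named", {
  cov <- sample_covariates(3, seed = 2)
  des <- assemble_design(cov, config = small_config(include_random = FALSE))
  expect_null(des$blocks$subject)
  expect_equal(des$p, des$n_fixed)
  cov$cadence <- NULL
  expect_error(assemble_design(cov, config = small_config()), "cadence")
})

test_that("tensor smooths are centred over the training covariates at each t", {
  cov <- sample_covariates(8, seed = 4)
  des <- assemble_design(cov, config = small_config(include_random = FALSE))
  set.seed(1)
  blk <- des$blocks$age
  beta_b <- rnorm(length(blk$cols))
  fitted <- as.numeric(des$X[, blk$cols] %*% beta_b)
  fmat <- matrix(fitted, nrow = 100)  # t x observations
  expect_lt(max(abs(rowMeans(fmat))), 1e-8)
})

test_that("noiseless intercept-only data are reproduced exactly", {
  # build the target curve inside the model's own spline space
  spec <- basis_spec(8, 3, c(0, 99))
  mu <- as.numeric(bspline_basis(0:99, spec) %*% c(0, 1, 3, 4, 2, 1, 0.5, 0))
  cov <- sample_covariates(3, seed = 5)
  curves <- data.frame(
    subject_id = rep(cov$subject_id, each = 100),
    obs_id = rep(cov$obs_id, each = 100),
    outcome = "hip_sagittal_angle",
    side = rep(cov$side, each = 100),
    speed_condition = rep(cov$speed_condition, each = 100),
    t = rep(0:99, nrow(cov)), value = rep(mu, nrow(cov))
  )
  cfg <- fosr_config(n_basis_t = 8, smooth_covariates = character(0),
                     include_random = FALSE, lambda = 1e-8)
  fit <- fit_fosr(curves, cov, config = cfg)
  beta0_hat <- as.numeric(bspline_basis(0:99, fit$blocks$intercept$spec_t) %*%
                            fit$coef_blocks$intercept)
  expect_equal(beta0_hat, mu, tolerance = 1e-6)
})

test_that("lambda -> 0 penalized fit matches a dense OLS oracle", {
  tr <- default_truth(sigma_eps = 0.5, sigma_b = 0)
  coh <- generate_cohort(12, seed = 7, tr)
  # age + speed only: cadence is collinear with speed/height by construction,
  # which would make the unpenalized normal equations ill-conditioned
  cfg <- small_config(include_random = FALSE, lambda = 1e-8,
                      smooth_covariates = c("age", "speed"))
  fit <- fit_fosr(coh$curves, coh$covariates, config = cfg)
  des <- assemble_design(coh$covariates, config = cfg)
  y <- gaitnorm:::align_response(coh$curves, coh$covariates,
                                 "hip_sagittal_angle", 0:99)
  ols <- stats::lm.fit(as.matrix(des$X), y)
  fitted_pen <- as.numeric(des$X %*% fit$coefficients)
  expect_lt(max(abs(fitted_pen - ols$fitted.values)), 1e-6)
})

test_that("penalized solution matches the dense closed form (property)", {
  tr <- default_truth(sigma_eps = 1, sigma_b = 1)
  coh <- generate_cohort(8, seed = 17, tr)
  cfg <- small_config()
  des <- assemble_design(coh$covariates, config = cfg)
  y <- gaitnorm:::align_response(coh$curves, coh$covariates,
                                 "hip_sagittal_angle", 0:99)
  ws <- gaitnorm:::fosr_workspace(des, y)
  set.seed(99)
  for (rep in 1:3) {
    lam <- setNames(10^runif(length(ws$entries), -2, 3), names(ws$entries))
    sol <- gaitnorm:::penalized_solve(ws, lam)
    beta_d <- oracle_penalized(des$X, y, ws$S_embedded,
                               rep(1, length(lam)) * lam)
    expect_lt(max(abs(sol$beta - beta_d)), 1e-8 * max(1, max(abs(beta_d))))
  }
})

test_that("residuals are orthogonal to the unpenalized columns", {
  sf <- shared_fit()
  des <- assemble_design(sf$cohort$covariates, config = sf$fit$config,
                         ranges = sf$fit$ranges)
  y <- gaitnorm:::align_response(sf$cohort$curves, sf$cohort$covariates,
                                 "hip_sagittal_angle", 0:99)
  r <- y - as.numeric(des$X %*% sf$fit$coefficients)
  g <- as.numeric(Matrix::crossprod(des$X, r))
  unpen <- c(des$blocks$sex$cols, des$blocks$side$cols)
  expect_lt(max(abs(g[unpen])), 1e-8 * sqrt(sum(y^2)))
})

test_that("increasing all smoothing parameters never improves the data fit", {
  tr <- default_truth(sigma_eps = 0.5, sigma_b = 0.5)
  coh <- generate_cohort(10, seed = 23, tr)
  cfg <- small_config()
  des <- assemble_design(coh$covariates, config = cfg)
  y <- gaitnorm:::align_response(coh$curves, coh$covariates,
                                 "hip_sagittal_angle", 0:99)
  ws <- gaitnorm:::fosr_workspace(des, y)
  rss <- sapply(10^seq(-3, 4, by = 1), function(l) {
    lam <- setNames(rep(l, length(ws$entries)), names(ws$entries))
    sol <- gaitnorm:::penalized_solve(ws, lam)
    sum((y - as.numeric(des$X %*% sol$beta))^2)
  })
  expect_true(all(diff(rss) >= -1e-8 * rss[-length(rss)]))
})

test_that("pure-noise responses are smoothed almost to the null space", {
  cov <- sample_covariates(15, seed = 31)
  cfg <- fosr_config(n_basis_t = 8, n_basis_x = 5, n_basis_tensor_t = 5,
                     smooth_covariates = c("age", "speed"),
                     include_random = FALSE)
  des <- assemble_design(cov, config = cfg)
  y <- withr::with_seed(44, rnorm(nrow(des$X)))
  sel <- select_smoothing(des, y, method = "REML")
  ws <- gaitnorm:::fosr_workspace(des, y)
  sol <- gaitnorm:::penalized_solve(ws, sel$lambda)
  # dense block-level effective degrees of freedom.  Each constrained tensor
  # block keeps a 2-dim unpenalized null space (linear-in-x times
  # constant/linear-in-t), so its edf cannot drop below 2; the penalized
  # part beyond the null space is what the criterion must suppress.
  Ad <- as.matrix(sol$A)
  H <- solve(Ad, as.matrix(ws$XtX))
  null_dim <- 2
  for (nm in c("age", "speed")) {
    edf_block <- sum(diag(H)[des$blocks[[nm]]$cols])
    expect_lt(edf_block - null_dim, 2)
    expect_lt(edf_block, 0.25 * length(des$blocks[[nm]]$cols))
  }
})

test_that("data-driven smoothing beats both extreme lambdas on a smooth signal", {
  # noise must be large enough that an unpenalized fit visibly overfits
  tr <- default_truth(sigma_eps = 2, sigma_b = 0)
  coh <- generate_cohort(12, seed = 53, tr)
  cfg <- fosr_config(n_basis_t = 12, n_basis_x = 6, n_basis_tensor_t = 6,
                     smooth_covariates = c("age", "speed"),
                     include_random = FALSE)
  truth_means <- t(sapply(seq_len(nrow(coh$covariates)), function(r) {
    true_mean_curve(coh$covariates[r, ], coh$truth[[1]])
  }))
  ise <- function(fit) {
    des <- assemble_design(coh$covariates, config = cfg)
    fitted <- matrix(as.numeric(des$X %*% fit$coefficients),
                     ncol = 100, byrow = TRUE)
    mean((fitted - truth_means)^2)
  }
  fit_sel <- fit_fosr(coh$curves, coh$covariates, config = cfg)
  cfg0 <- cfg; cfg0$lambda <- 1e-6
  cfg_inf <- cfg; cfg_inf$lambda <- 1e8
  expect_lt(ise(fit_sel), ise(fit_fosr(coh$curves, coh$covariates, config = cfg0)))
  expect_lt(ise(fit_sel), ise(fit_fosr(coh$curves, coh$covariates, config = cfg_inf)))
})

test_that("GCV and REML agree on the order of magnitude of key lambdas", {
  # noise must be appreciable so both criteria have interior optima; with
  # near-noiseless data the score is flat for all small lambdas and the
  # selected values are arbitrary within the plateau
  tr <- default_truth(sigma_eps = 4, sigma_b = 0)
  coh <- generate_cohort(15, seed = 61, tr)
  cfg <- fosr_config(n_basis_t = 8, n_basis_x = 5, n_basis_tensor_t = 5,
                     smooth_covariates = "age", include_random = FALSE)
  des <- assemble_design(coh$covariates, config = cfg)
  y <- gaitnorm:::align_response(coh$curves, coh$covariates,
                                 "hip_sagittal_angle", 0:99)
  reml <- select_smoothing(des, y, method = "REML")
  gcv <- select_smoothing(des, y, method = "GCV")
  for (nm in names(reml$lambda)) {
    expect_lt(abs(log10(reml$lambda[[nm]]) - log10(gcv$lambda[[nm]])), 2.5,
              label = paste("lambda", nm))
  }
})

test_that("sigma2 and the coefficient covariance are valid", {
  fit <- shared_fit()$fit
  expect_gt(fit$sigma2, 0)
  expect_true(all(fit$lambda >= 0))
  V <- fit$Vb_fixed
  expect_equal(V, t(V), tolerance = 1e-10)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8 * max(ev)))
})

test_that("refit_full is the same fit flagged for deployment", {
  sf <- shared_fit()
  full <- refit_full(sf$cohort$curves, sf$cohort$covariates,
                     config = sf$fit$config, ranges = sf$fit$ranges)
  expect_true(full$metadata$deployment)
  expect_false(sf$fit$metadata$deployment)
  expect_equal(full$coefficients, sf$fit$coefficients, tolerance = 1e-12)
  expect_equal(full$metadata$n, length(unique(sf$cohort$covariates$subject_id)))
  # deployment guard-rail: refuses evaluation on its own training subjects
  expect_error(
    evaluate_model(full, sf$cohort$curves, sf$cohort$covariates),
    "deployment"
  )
  rep <- evaluate_model(full, sf$cohort$curves, sf$cohort$covariates,
                        allow_overlap = TRUE)
  expect_s3_class(rep, "evaluation_report")
})

test_that("mismatched curves and covariates are rejected", {
  sf <- shared_fit()
  cov <- sf$cohort$covariates
  curves <- sf$cohort$curves
  expect_error(fit_fosr(curves[curves$t != 50, ], cov, config = sf$fit$config),
               "complete curve")
  cov2 <- cov; cov2$obs_id[1] <- "nonexistent"
  expect_error(fit_fosr(curves, cov2, config = sf$fit$config), "complete curve")
})
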