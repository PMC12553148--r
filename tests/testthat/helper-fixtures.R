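# Shared fixtures, built in code and memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, value_fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- value_fn()
  .fixture_env[[key]]
}

small_config <- function(...) {
  fosr_config(n_basis_t = 8L, n_basis_x = 5L, n_basis_tensor_t = 5L, ...)
}

# truth with all covariate effects switched off and a spline-free intercept
zero_truth <- function(beta0 = function(t) sin(2 * pi * t / 100),
                       sigma_eps = 0, sigma_b = 0) {
  tr <- default_truth(sigma_eps = sigma_eps, sigma_b = sigma_b)
  tr$beta0 <- beta0
  tr$f <- lapply(tr$f, function(f) function(x, t) 0 * t + 0 * x[1])
  tr$beta_sex <- 0
  tr$beta_side <- 0
  if (sigma_b == 0) tr$subject_coef_sd <- 0
  tr
}

# the generator's full covariate support, for fits that must accept any
# profile the generator can produce
truth_ranges <- function(tr) lapply(tr$params$ranges, as.numeric)

# a modest shared cohort + fixed-lambda fit reused by prediction tests
shared_fit <- function() {
  memo("shared_fit", function() {
    tr <- default_truth(sigma_eps = 0.5, sigma_b = 1)
    coh <- generate_cohort(25, 42, tr)
    cfg <- small_config(lambda = 1)
    fit <- fit_fosr(coh$curves, coh$covariates, config = cfg,
                    ranges = truth_ranges(tr))
    list(truth = tr, cohort = coh, fit = fit)
  })
}
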