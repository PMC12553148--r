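# Build the fixed-effect design rows of one covariate profile over a grid.
fixed_design_rows <- function(fit, rec, t_grid = fit$t_grid) {
  rec <- as.list(rec)
  for (f in required_covariate_fields()) {
    if (f == "subject_id") next
    if (is.null(rec[[f]])) stop_invalid("profile is missing covariate `", f, "`")
  }
  for (nm in names(fit$ranges)) {
    r <- fit$ranges[[nm]]
    x <- rec[[nm]]
    if (x < r[1] || x > r[2]) {
      stop_invalid("covariate `", nm, "` = ", signif(x, 6),
                   " outside the supported range [", signif(r[1], 6), ", ",
                   signif(r[2], 6), "] of the training data")
    }
  }
  n_t <- length(t_grid)
  parts <- vector("list", 0L)
  for (bn in names(fit$blocks)) {
    blk <- fit$blocks[[bn]]
    part <- switch(blk$type,
      time = bspline_basis(t_grid, blk$spec_t),
      tensor = {
        bx <- bspline_basis(rec[[blk$x_name]], blk$spec_x) %*% blk$transform
        row_kronecker(matrix(bx, n_t, ncol(bx), byrow = TRUE),
                      bspline_basis(t_grid, blk$spec_t))
      },
      scalar = matrix(
        if (bn == "sex") as.numeric(rec$sex == "female")
        else as.numeric(rec$side == "right"),
        n_t, 1L
      ),
      random = NULL
    )
    if (!is.null(part)) parts[[bn]] <- part
  }
  M <- do.call(cbind, parts)
  stopifnot(ncol(M) == fit$n_fixed)
  M
}

new_predicted_curve <- function(fit, rec, t_grid, mean, lower, upper, sd,
                                level = NA_real_, kind = NA_character_) {
  structure(
    list(
      outcome = fit$outcome, units = fit$units, covariates = as.list(rec),
      level = level, kind = kind,
      table = data.frame(t = t_grid, mean = mean, lower95 = lower,
                         upper95 = upper, sd = sd)
    ),
    class = "predicted_curve"
  )
}

#' Predict the normative mean waveform for a covariate profile
#'
#' Evaluates the fitted population-level mean
#' `beta0(t) + sum_f f(x, t) + beta_sex I(female) + beta_side I(right)`
#' on the gait-cycle grid.  The subject random intercept is set to zero:
#' predictions are normative curves for new, unseen individuals.  Covariates
#' must lie within the (slightly extended) training ranges.
#'
#' @param fit an [fit_fosr()] result.
#' @param new_cov covariate profile: named list or one-row data.frame with
#'   `sex`, `age`, `speed`, `mass`, `height`, `cadence`, `side`.
#' @param t_grid evaluation grid (default the fit's grid).
#' @return a `predicted_curve` whose `table` has columns `t` and `mean`
#'   (band columns are `NA`; see [predict_band()]).
#' @export
predict_mean <- function(fit, new_cov, t_grid = fit$t_grid) {
  stopifnot(inherits(fit, "fosr_fit"))
  M <- fixed_design_rows(fit, new_cov, t_grid)
  mu <- as.numeric(M %*% fit$coefficients[seq_len(fit$n_fixed)])
  new_predicted_curve(fit, new_cov, t_grid, mu, NA_real_, NA_real_, NA_real_)
}

#' Predict a waveform with a pointwise uncertainty band
#'
#' `kind = "ci"` returns the pointwise Wald confidence band for the mean,
#' `mean +/- z * se(t)`, with the standard error from the Bayesian
#' coefficient covariance.  `kind = "sd"` returns a population spread band
#' `mean +/- sd(t)` where
#' `sd(t)^2 = prediction variance + Var(b_i(t)) + sigma^2`, i.e. the
#' expected spread of individual observed curves around the normative mean.
#'
#' @inheritParams predict_mean
#' @param level confidence level in (0, 1), default 0.95 (`kind = "ci"` only).
#' @param kind `"ci"` or `"sd"`.
#' @return a `predicted_curve` with `mean`, `lower95`, `upper95` and `sd`
#'   columns filled in (`sd` holds `se(t)` for `"ci"` and the population SD
#'   for `"sd"`).
#' @export
predict_band <- function(fit, new_cov, level = 0.95, kind = c("ci", "sd"),
                         t_grid = fit$t_grid) {
  stopifnot(inherits(fit, "fosr_fit"))
  kind <- match.arg(kind)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop_invalid("`level` must be in (0, 1)")
  }
  M <- fixed_design_rows(fit, new_cov, t_grid)
  mu <- as.numeric(M %*% fit$coefficients[seq_len(fit$n_fixed)])
  se_fit <- sqrt(pmax(rowSums((M %*% fit$Vb_fixed) * M), 0))
  if (kind == "ci") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    new_predicted_curve(fit, new_cov, t_grid,
                        mu, mu - z * se_fit, mu + z * se_fit, se_fit,
                        level = level, kind = "ci")
  } else {
    var_b <- if (fit$config$include_random) {
      Bt <- bspline_basis(t_grid, fit$blocks$intercept$spec_t)
      fit$sigma2_b * rowSums(Bt^2)
    } else 0
    sd_pop <- sqrt(se_fit^2 + var_b + fit$sigma2)
    new_predicted_curve(fit, new_cov, t_grid,
                        mu, mu - sd_pop, mu + sd_pop, sd_pop,
                        level = level, kind = "sd")
  }
}

#' @export
print.predicted_curve <- function(x, ...) {
  cat("Predicted", x$outcome, "curve (", x$units, ")",
      if (!is.na(x$kind)) paste0("with ", x$kind, " band"), "\n")
  print(utils::head(x$table, 5))
  cat("... (", nrow(x$table), " grid points)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.predicted_curve <- function(x, ...) x$table

#' Empirical quantiles of a training covariate
#'
#' Linear-interpolation quantiles of the order statistics (R's type 7
#' definition), the convention used when choosing evaluation values for
#' smooth-effect plots.
#'
#' @param covariates covariate table.
#' @param name covariate column name.
#' @param probs probabilities, default the 25th/50th/75th percentiles.
#' @return numeric vector of quantile values.
#' @export
covariate_quantiles <- function(covariates, name, probs = c(0.25, 0.5, 0.75)) {
  if (is.null(covariates[[name]]) || length(covariates[[name]]) == 0L) {
    stop_invalid("no values available for covariate `", name, "`")
  }
  stats::quantile(covariates[[name]], probs = probs, names = FALSE, type = 7)
}

#' Extract a fitted covariate-by-time smooth effect
#'
#' Evaluates the centred surface `f(x, t)` of one continuous covariate at
#' chosen covariate values (defaulting to the training 25th/50th/75th
#' quantiles) with a pointwise 95% confidence band from the block's
#' coefficient covariance.  The intercept and all other terms are excluded,
#' so the curves show the isolated association of the covariate; by the
#' sum-to-zero identifiability constraint they average to zero over the
#' training covariate values at every t.
#'
#' @param fit an `fosr_fit`.
#' @param covariate one of the fitted smooth covariates (`age`, `speed`,
#'   `cadence`, `height`, `mass`).  Naming `sex` or `side` is an error:
#'   those are scalar coefficients, see [scalar_effects()].
#' @param values covariate values at which to evaluate; default the training
#'   quantiles stored in the fit.
#' @param t_grid evaluation grid.
#' @param level confidence level of the pointwise band.
#' @return a data.frame of class `smooth_effect` with columns `covariate`,
#'   `x`, `t`, `estimate`, `se`, `lower95`, `upper95`.
#' @export
extract_smooth_effect <- function(fit, covariate, values = NULL,
                                  t_grid = fit$t_grid, level = 0.95) {
  stopifnot(inherits(fit, "fosr_fit"))
  if (covariate %in% c("sex", "side")) {
    stop_invalid("`", covariate, "` is a scalar (time-constant) effect, not ",
                 "a smooth; use scalar_effects(fit)")
  }
  blk <- fit$blocks[[covariate]]
  if (is.null(blk) || blk$type != "tensor") {
    stop_invalid("`", covariate, "` is not a fitted smooth term; available: ",
                 paste(names(Filter(function(b) b$type == "tensor",
                                    fit$blocks)), collapse = ", "))
  }
  values <- values %||% fit$metadata$quantiles[[covariate]]
  z <- stats::qnorm(1 - (1 - level) / 2)
  Bt <- bspline_basis(t_grid, blk$spec_t)
  Vb <- fit$Vb_fixed[blk$cols, blk$cols, drop = FALSE]
  beta_b <- fit$coefficients[blk$cols]
  out <- lapply(values, function(x) {
    bx <- bspline_basis(x, blk$spec_x) %*% blk$transform
    M <- row_kronecker(matrix(bx, length(t_grid), ncol(bx), byrow = TRUE), Bt)
    est <- as.numeric(M %*% beta_b)
    se <- sqrt(pmax(rowSums((M %*% Vb) * M), 0))
    data.frame(covariate = covariate, x = x, t = t_grid, estimate = est,
               se = se, lower95 = est - z * se, upper95 = est + z * se)
  })
  res <- do.call(rbind, out)
  class(res) <- c("smooth_effect", class(res))
  res
}

#' Time-constant scalar effects with confidence intervals
#'
#' @param fit an `fosr_fit`.
#' @param level confidence level.
#' @return data.frame with one row per scalar term (`sex`: female vs male;
#'   `side`: right vs left) and columns `term`, `estimate`, `se`, `lower`,
#'   `upper`.
#' @export
scalar_effects <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(c("sex", "side"), function(nm) {
    cols <- fit$blocks[[nm]]$cols
    est <- fit$coefficients[cols]
    se <- sqrt(fit$Vb_fixed[cols, cols])
    data.frame(term = nm, estimate = est, se = se,
               lower = est - z * se, upper = est + z * se)
  })
  do.call(rbind, rows)
}
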