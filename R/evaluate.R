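#' Participant-level train/test split
#'
#' Splits subject ids (never individual observations) into training and
#' test sets: all observations of a subject follow the subject.  The
#' training set size is `floor(train_fraction * n)`.
#'
#' @param ids vector of unique subject ids (>= 2).
#' @param train_fraction fraction of subjects assigned to training,
#'   in (0, 1); default 0.8.
#' @param seed integer seed; the assignment is reproducible.
#' @return an object of class `split_assignment` with `train_ids`,
#'   `test_ids`, `seed` and `train_fraction`.
#' @export
split_participants <- function(ids, train_fraction = 0.8, seed = 1L) {
  ids <- unique(as.character(ids))
  if (length(ids) < 2L) stop_invalid("need at least 2 unique subject ids")
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop_invalid("`train_fraction` must be in (0, 1)")
  }
  n_train <- floor(train_fraction * length(ids))
  if (n_train < 1L || n_train >= length(ids)) {
    stop_invalid("`train_fraction` leaves an empty training or test set")
  }
  train <- with_seed(seed, sample(ids, n_train))
  structure(
    list(
      train_ids = sort(train), test_ids = sort(setdiff(ids, train)),
      seed = seed, train_fraction = train_fraction
    ),
    class = "split_assignment"
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("participant split: %d train / %d test (fraction %.2f, seed %s)\n",
              length(x$train_ids), length(x$test_ids), x$train_fraction,
              format(x$seed)))
  invisible(x)
}

curve_values <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.list(x) && !is.null(x$values)) return(as.numeric(x$values))
  if (is.data.frame(x) && !is.null(x$value)) return(as.numeric(x$value[order(x$t)]))
  stop_invalid("cannot interpret curve input; supply a numeric vector")
}

resolve_window <- function(n, window = NULL) {
  if (is.null(window)) return(seq_len(n))
  window <- as.integer(window)
  if (any(window < 0L | window >= n)) {
    stop_invalid("evaluation window indices must lie in [0, ", n - 1L, "]")
  }
  window + 1L
}

#' Curve-level root mean squared error
#'
#' The root integrated mean squared error between an observed and a
#' predicted waveform, discretised as the square root of the mean squared
#' pointwise difference over the evaluation window (rectangle rule).  The
#' default window is the full 100-point cycle; `window` (a vector of t
#' values) restricts it, e.g. to the stance phase.
#'
#' @param obs,pred observed and predicted curves: numeric vectors of equal
#'   length (or objects carrying `$values`).
#' @param window optional integer vector of t indices (0-based) to evaluate
#'   over.
#' @return non-negative scalar, in outcome units.
#' @export
rmse_curve <- function(obs, pred, window = NULL) {
  o <- curve_values(obs)
  p <- curve_values(pred)
  if (length(o) != length(p)) {
    stop_invalid("grid mismatch: obs has ", length(o), " points, pred has ",
                 length(p))
  }
  i <- resolve_window(length(o), window)
  sqrt(mean((o[i] - p[i])^2))
}

#' Curve-level relative RMSE (percent)
#'
#' RMSE divided by the average of the observed and predicted curve ranges
#' over the window, expressed as a percentage:
#' `RMSE / (0.5 * (range(obs) + range(pred))) * 100`.
#'
#' @inheritParams rmse_curve
#' @return non-negative percentage.
#' @export
relrmse_curve <- function(obs, pred, window = NULL) {
  o <- curve_values(obs)
  p <- curve_values(pred)
  if (length(o) != length(p)) {
    stop_invalid("grid mismatch: obs has ", length(o), " points, pred has ",
                 length(p))
  }
  i <- resolve_window(length(o), window)
  denom <- 0.5 * ((max(o[i]) - min(o[i])) + (max(p[i]) - min(p[i])))
  if (denom == 0) {
    stop_invalid("both curves are constant over the window; relRMSE undefined")
  }
  rmse_curve(o, p, window) / denom * 100
}

#' Curve-level Pearson correlation
#'
#' Pearson correlation of the two waveforms over the window; returns `NA`
#' (the undefined flag) when either curve has zero variance.
#'
#' @inheritParams rmse_curve
#' @return correlation in \[-1, 1\], or `NA` when undefined.
#' @export
pearson_curve <- function(obs, pred, window = NULL) {
  o <- curve_values(obs)
  p <- curve_values(pred)
  if (length(o) != length(p)) {
    stop_invalid("grid mismatch: obs has ", length(o), " points, pred has ",
                 length(p))
  }
  i <- resolve_window(length(o), window)
  if (stats::sd(o[i]) == 0 || stats::sd(p[i]) == 0) return(NA_real_)
  stats::cor(o[i], p[i])
}

#' Evaluate a fitted model on held-out test curves
#'
#' For every test observation, predicts the normative mean waveform (subject
#' intercept set to zero) and computes the three accuracy metrics against
#' the observed curve; aggregates mean and SD of each metric across test
#' curves, reporting undefined correlations as exclusions.  Refuses subject
#' leakage: test subjects must be disjoint from the fit's training subjects
#' unless `allow_overlap = TRUE`.
#'
#' @param fit an `fosr_fit`.
#' @param test_curves long curve table of the test set.
#' @param test_covariates covariate table of the test set.
#' @param window optional evaluation window (0-based t values).
#' @param allow_overlap override the subject-leakage guard.
#' @param clamp clamp test covariates that fall marginally outside the fit's
#'   supported range to the range boundary (counted in the summary as
#'   `n_clamped`) instead of failing; default `TRUE`.
#' @return object of class `evaluation_report`: list with `per_curve` (one
#'   row per test curve) and `summary` (one row: mean and SD of RMSE,
#'   relRMSE, correlation, plus exclusion count).
#' @export
evaluate_model <- function(fit, test_curves, test_covariates, window = NULL,
                           allow_overlap = FALSE, clamp = TRUE) {
  stopifnot(inherits(fit, "fosr_fit"))
  validate_covariates(test_covariates)
  overlap <- intersect(unique(test_covariates$subject_id),
                       fit$metadata$subjects)
  if (length(overlap) && !allow_overlap) {
    stop_invalid(
      if (isTRUE(fit$metadata$deployment)) {
        "deployment fits are trained on all subjects; "
      } else "",
      length(overlap), " test subject(s) were in the training set (e.g. ",
      overlap[1], "); use allow_overlap = TRUE to override"
    )
  }
  n_clamped <- 0L
  if (clamp) {
    for (nm in names(fit$ranges)) {
      r <- fit$ranges[[nm]]
      out <- test_covariates[[nm]] < r[1] | test_covariates[[nm]] > r[2]
      n_clamped <- n_clamped + sum(out)
      test_covariates[[nm]] <- pmin(pmax(test_covariates[[nm]], r[1]), r[2])
    }
  }
  t_grid <- fit$t_grid
  cu <- test_curves[test_curves$outcome == fit$outcome, , drop = FALSE]
  if (nrow(cu) == 0L) stop_invalid("no test curves for outcome `", fit$outcome, "`")
  key <- paste(cu$obs_id, cu$t)
  rows <- lapply(seq_len(nrow(test_covariates)), function(r) {
    rec <- test_covariates[r, ]
    idx <- match(paste(rec$obs_id, t_grid), key)
    if (anyNA(idx)) {
      stop_invalid("incomplete test curve for observation ", rec$obs_id)
    }
    obs <- cu$value[idx]
    pred <- predict_mean(fit, rec)$table$mean
    data.frame(
      obs_id = rec$obs_id, subject_id = rec$subject_id, outcome = fit$outcome,
      rmse = rmse_curve(obs, pred, window),
      relrmse = tryCatch(relrmse_curve(obs, pred, window),
                         error = function(e) NA_real_),
      correlation = pearson_curve(obs, pred, window),
      stringsAsFactors = FALSE
    )
  })
  per_curve <- do.call(rbind, rows)
  cor_ok <- !is.na(per_curve$correlation)
  n_excl <- sum(!cor_ok)
  if (n_excl > 0) {
    warning(n_excl, " curve(s) with undefined correlation excluded from ",
            "aggregation", call. = FALSE)
  }
  summary <- data.frame(
    outcome = fit$outcome, units = fit$units, n_curves = nrow(per_curve),
    rmse_mean = mean(per_curve$rmse), rmse_sd = stats::sd(per_curve$rmse),
    relrmse_mean = mean(per_curve$relrmse, na.rm = TRUE),
    relrmse_sd = stats::sd(per_curve$relrmse, na.rm = TRUE),
    cor_mean = mean(per_curve$correlation[cor_ok]),
    cor_sd = stats::sd(per_curve$correlation[cor_ok]),
    n_excluded = n_excl, n_clamped = n_clamped,
    stringsAsFactors = FALSE
  )
  structure(list(per_curve = per_curve, summary = summary),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat("Evaluation of", s$outcome, "on", s$n_curves, "test curves\n")
  cat(sprintf("  RMSE    %.3f (%.3f) %s\n", s$rmse_mean, s$rmse_sd, s$units))
  cat(sprintf("  relRMSE %.2f (%.2f) %%\n", s$relrmse_mean, s$relrmse_sd))
  cat(sprintf("  cor     %.3f (%.3f)%s\n", s$cor_mean, s$cor_sd,
              if (s$n_excluded > 0) paste0("  [", s$n_excluded, " excluded]")
              else ""))
  invisible(x)
}
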