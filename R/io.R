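# CSV schemas (UTF-8, comma separated, '.' decimal, mandatory header):
#   curves:     subject_id, outcome, side, speed_condition, t, value
#               (optional obs_id; derived as subject_id_condition_side)
#   covariates: subject_id, sex, age, speed, mass, height, cadence, side,
#               speed_condition (optional obs_id)

derive_obs_id <- function(df) {
  if (is.null(df$obs_id)) {
    df$obs_id <- paste(df$subject_id, df$speed_condition, df$side, sep = "_")
  }
  df
}

#' Read and validate a long-format curve table
#'
#' Each curve must cover the gait-cycle grid `t = 0..99` exactly once;
#' violations are reported with the offending observation and t values.
#'
#' @param path CSV path.
#' @return validated data.frame with an `obs_id` column.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_curve_table(df)
}

validate_curve_table <- function(df) {
  need <- c("subject_id", "outcome", "side", "speed_condition", "t", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_invalid("curve table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))
    stop_invalid("non-numeric `value` at row(s) ",
                 paste(utils::head(bad, 3), collapse = ", "))
  }
  if (anyNA(df$value) || any(!is.finite(df$value))) {
    bad <- which(!is.finite(df$value))
    stop_invalid("missing/non-finite `value` at row(s) ",
                 paste(utils::head(bad, 3), collapse = ", "))
  }
  unknown <- setdiff(unique(df$outcome), gait_outcomes()$outcome)
  if (length(unknown)) {
    stop_invalid("unknown outcome name(s): ", paste(unknown, collapse = ", "))
  }
  df <- derive_obs_id(df)
  t_grid <- gait_t_grid()
  spl <- split(df$t, paste(df$obs_id, df$outcome))
  for (k in names(spl)) {
    tt <- spl[[k]]
    if (length(tt) != length(t_grid) || !setequal(tt, t_grid) ||
        anyDuplicated(tt)) {
      missing_t <- setdiff(t_grid, tt)
      dup_t <- unique(tt[duplicated(tt)])
      stop_invalid(
        "curve ", k, " does not cover t = 0..99 exactly once",
        if (length(missing_t)) paste0(" (missing t: ",
                                      paste(utils::head(missing_t, 5),
                                            collapse = ", "), ")"),
        if (length(dup_t)) paste0(" (duplicated t: ",
                                  paste(utils::head(dup_t, 5),
                                        collapse = ", "), ")")
      )
    }
  }
  df
}

#' @rdname read_curves
#' @param curves curve table to write.
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a covariate table
#'
#' @param path CSV path.
#' @return validated data.frame with an `obs_id` column.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in c("age", "speed", "mass", "height", "cadence")) {
    if (!is.null(df[[f]]) && !is.numeric(df[[f]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[f]]))))
      stop_invalid("non-numeric `", f, "` at row(s) ",
                   paste(utils::head(bad, 3), collapse = ", "))
    }
  }
  validate_covariates(df)
  derive_obs_id(df)
}

#' @rdname read_covariates
#' @param covariates covariate table to write.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- fit serialization -----------------------------------------------------

FIT_BUNDLE_VERSION <- "1"

write_num <- function(x, path) {
  writeLines(sprintf("%.17g", as.numeric(x)), path)
}

write_mat <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
}

read_mat <- function(path) {
  rows <- strsplit(readLines(path), " ", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

spec_to_list <- function(s) {
  list(n_basis = s$n_basis, degree = s$degree, domain = s$domain)
}
spec_from_list <- function(l) basis_spec(l$n_basis, l$degree, as.numeric(l$domain))

#' Save / load a fitted model bundle
#'
#' Writes the fit as a directory bundle: `manifest.json` (structure,
#' smoothing parameters, metadata — full numeric precision) plus plain-text
#' arrays (`coefficients.txt`, `Vb_fixed.txt`, one constraint transform per
#' smooth).  `load_fosr_fit()` reconstructs a fit whose predictions are
#' bit-identical to the original's.
#'
#' @param fit an `fosr_fit`.
#' @param path bundle directory (created if needed).
#' @return `save_fosr_fit` returns `path` invisibly; `load_fosr_fit`
#'   returns the `fosr_fit`.
#' @export
save_fosr_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fosr_fit"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  blocks <- lapply(fit$blocks, function(b) {
    out <- list(type = b$type, cols = b$cols)
    if (!is.null(b$x_name)) out$x_name <- b$x_name
    if (!is.null(b$spec_x)) out$spec_x <- spec_to_list(b$spec_x)
    if (!is.null(b$spec_t)) out$spec_t <- spec_to_list(b$spec_t)
    if (!is.null(b$subjects)) out$subjects <- b$subjects
    out
  })
  manifest <- list(
    bundle_version = FIT_BUNDLE_VERSION,
    outcome = fit$outcome, units = fit$units,
    n_fixed = fit$n_fixed, p = fit$p,
    lambda = as.list(fit$lambda),
    smoothing = fit$smoothing[setdiff(names(fit$smoothing), "trace")],
    sigma2 = fit$sigma2, sigma2_b = fit$sigma2_b, edf = fit$edf,
    rss_pen = fit$rss_pen,
    t_grid = fit$t_grid, ranges = fit$ranges,
    config = fit$config[setdiff(names(fit$config), "optim_control")],
    metadata = fit$metadata,
    blocks = blocks
  )
  # I(17): 17 significant digits round-trip doubles exactly, so loaded fits
  # reproduce predictions bit-identically
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       force = TRUE)
  write_num(fit$coefficients, file.path(path, "coefficients.txt"))
  write_mat(fit$Vb_fixed, file.path(path, "Vb_fixed.txt"))
  for (nm in names(fit$blocks)) {
    tr <- fit$blocks[[nm]]$transform
    if (!is.null(tr)) {
      write_mat(tr, file.path(path, paste0("transform_", nm, ".txt")))
    }
  }
  invisible(path)
}

#' @rdname save_fosr_fit
#' @export
load_fosr_fit <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(as.character(man$bundle_version), FIT_BUNDLE_VERSION)) {
    stop_invalid("unsupported fit bundle version: ", man$bundle_version)
  }
  blocks <- lapply(seq_along(man$blocks), function(i) {
    b <- man$blocks[[i]]
    out <- list(type = b$type, cols = as.integer(b$cols))
    if (!is.null(b$x_name)) out$x_name <- b$x_name
    if (!is.null(b$spec_x)) out$spec_x <- spec_from_list(b$spec_x)
    if (!is.null(b$spec_t)) out$spec_t <- spec_from_list(b$spec_t)
    if (!is.null(b$subjects)) out$subjects <- b$subjects
    nm <- names(man$blocks)[i]
    tfile <- file.path(path, paste0("transform_", nm, ".txt"))
    if (file.exists(tfile)) out$transform <- read_mat(tfile)
    out
  })
  names(blocks) <- names(man$blocks)
  cfg <- man$config
  config <- fosr_config(
    n_basis_t = cfg$n_basis_t, n_basis_x = cfg$n_basis_x,
    n_basis_tensor_t = cfg$n_basis_tensor_t, degree = cfg$degree,
    penalty_order = cfg$penalty_order,
    smooth_covariates = cfg$smooth_covariates,
    include_random = cfg$include_random, smoothing = cfg$smoothing,
    lambda = if (length(cfg$lambda)) unlist(cfg$lambda) else NULL,
    domain_extend = cfg$domain_extend
  )
  coefficients <- as.numeric(readLines(file.path(path, "coefficients.txt")))
  metadata <- man$metadata
  metadata$quantiles <- lapply(metadata$quantiles, as.numeric)
  structure(
    list(
      outcome = man$outcome, units = man$units,
      coefficients = coefficients,
      coef_blocks = lapply(blocks, function(b) coefficients[b$cols]),
      blocks = blocks,
      n_fixed = as.integer(man$n_fixed), p = as.integer(man$p),
      lambda = unlist(man$lambda), smoothing = man$smoothing,
      Vb_fixed = read_mat(file.path(path, "Vb_fixed.txt")),
      sigma2 = man$sigma2, sigma2_b = man$sigma2_b, edf = man$edf,
      rss_pen = man$rss_pen,
      t_grid = if (all(man$t_grid == round(man$t_grid))) {
        as.integer(man$t_grid)
      } else {
        as.numeric(man$t_grid)
      },
      ranges = lapply(man$ranges, as.numeric),
      config = config, metadata = metadata
    ),
    class = "fosr_fit"
  )
}

# ---- report / effect / prediction export -----------------------------------

#' Export a predicted curve
#'
#' @param pred a `predicted_curve`.
#' @param path output path; `.json` gets a JSON document, anything else CSV
#'   with columns `t, mean, lower95, upper95, sd`.
#' @export
write_prediction <- function(pred, path) {
  stopifnot(inherits(pred, "predicted_curve"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(outcome = pred$outcome, units = pred$units,
           covariates = pred$covariates, level = pred$level,
           kind = pred$kind, curve = pred$table),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
    )
  } else {
    utils::write.csv(pred$table, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export an evaluation report
#'
#' Writes the per-outcome summary (mean and SD of RMSE, relRMSE and
#' correlation across test curves) as CSV, and optionally the full
#' per-curve table plus summary as JSON.
#'
#' @param reports one `evaluation_report` or a list of them (one per outcome).
#' @param path_csv summary CSV path.
#' @param path_json optional JSON path.
#' @export
write_report <- function(reports, path_csv, path_json = NULL) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  summary <- do.call(rbind, lapply(reports, `[[`, "summary"))
  utils::write.csv(summary, path_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(summary = summary,
           per_curve = do.call(rbind, lapply(reports, `[[`, "per_curve"))),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
    )
  }
  invisible(path_csv)
}

#' Plot a predicted curve with its uncertainty band
#'
#' @param x a `predicted_curve`.
#' @param ... passed to [plot()].
#' @export
plot.predicted_curve <- function(x, ...) {
  tb <- x$table
  has_band <- !all(is.na(tb$lower95))
  ylim <- if (has_band) range(tb$lower95, tb$upper95) else range(tb$mean)
  plot(tb$t, tb$mean, type = "n", xlab = "gait cycle (%)",
       ylab = paste0(x$outcome, " (", x$units, ")"), ylim = ylim, ...)
  if (has_band) {
    graphics::polygon(c(tb$t, rev(tb$t)), c(tb$lower95, rev(tb$upper95)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  }
  graphics::lines(tb$t, tb$mean, col = "steelblue", lwd = 2)
  invisible(x)
}
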