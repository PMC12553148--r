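#' Pipeline configuration
#'
#' The YAML-backed configuration tying the pipeline stages together.  The
#' defaults reproduce the study design: an 80:20 participant split,
#' smooth-effect evaluation at the 25th/50th/75th covariate quantiles, 95%
#' uncertainty level, full-cycle evaluation window, REML smoothing.
#'
#' @param overrides named list (or path to a YAML file via
#'   [read_pipeline_config()]) overriding the defaults; unknown keys are an
#'   error.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    n_subjects = 50L,
    outcomes = "hip_sagittal_angle",
    split = list(train_fraction = 0.8, seed = 1L),
    model = list(
      n_basis_t = 20L, n_basis_x = 8L, n_basis_tensor_t = 8L,
      degree = 3L, penalty_order = 2L, smoothing = "REML",
      include_random = TRUE, lambda = NULL
    ),
    evaluation = list(window = NULL),
    quantile_probs = c(0.25, 0.5, 0.75),
    level = 0.95
  )
  cfg <- merge_config(cfg, overrides, path = "")
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(base, overrides, path) {
  if (is.null(overrides)) return(base)
  if (!is.list(overrides)) stop_invalid("config overrides must be a list")
  for (nm in names(overrides)) {
    if (!nm %in% names(base)) {
      stop_invalid("unknown config key: ", paste0(path, nm))
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]],
                                 paste0(path, nm, "."))
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

validate_pipeline_config <- function(cfg) {
  check_count(cfg$seed, "seed", min = 0L)
  check_count(cfg$n_subjects, "n_subjects", min = 1L)
  f <- cfg$split$train_fraction
  if (!is.numeric(f) || f <= 0 || f >= 1) {
    stop_invalid("split.train_fraction must be in (0, 1)")
  }
  if (!identical(cfg$outcomes, "all")) {
    bad <- setdiff(cfg$outcomes, gait_outcomes()$outcome)
    if (length(bad)) stop_invalid("unknown outcome(s) in config: ",
                                  paste(bad, collapse = ", "))
  }
  if (!cfg$model$smoothing %in% c("REML", "GCV")) {
    stop_invalid("model.smoothing must be 'REML' or 'GCV'")
  }
  if (!is.numeric(cfg$quantile_probs) || any(cfg$quantile_probs <= 0) ||
      any(cfg$quantile_probs >= 1)) {
    stop_invalid("quantile_probs must lie in (0, 1)")
  }
  if (cfg$level <= 0 || cfg$level >= 1) stop_invalid("level must be in (0, 1)")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path YAML file of overrides.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  pipeline_config(yaml::read_yaml(path))
}

config_outcomes <- function(cfg) {
  if (identical(cfg$outcomes, "all")) gait_outcomes()$outcome else cfg$outcomes
}

model_config_from_pipeline <- function(cfg) {
  m <- cfg$model
  fosr_config(
    n_basis_t = m$n_basis_t, n_basis_x = m$n_basis_x,
    n_basis_tensor_t = m$n_basis_tensor_t, degree = m$degree,
    penalty_order = m$penalty_order, smoothing = m$smoothing,
    include_random = m$include_random,
    lambda = if (length(m$lambda)) unlist(m$lambda) else NULL
  )
}
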