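#' Ground-truth effect surfaces for the synthetic gait generator
#'
#' A `simulation_truth` bundles every term of the generating
#' function-on-scalar model for one outcome: a time-varying intercept
#' `beta0(t)`, five covariate-by-time smooth surfaces (age, speed, cadence,
#' height, mass), time-constant scalar effects of sex and side, the subject
#' random-intercept magnitude `sigma_b` (pooled SD of the smooth subject
#' curves, in outcome units) and the grid-point noise SD `sigma_eps`.  Every
#' smooth surface is numerically centred so it integrates to ~0 over the
#' supported covariate range at each t, matching the identifiability
#' convention of the fitted model.
#'
#' Default amplitudes are scaled per outcome family so that waveforms have
#' realistic magnitudes: peak-to-peak roughly 30 deg for angles, 10 N/kg for
#' vertical GRF, 2 N/kg for anterior-posterior GRF, 1.5 Nm/kg for moments and
#' 3 W/kg for powers; `sigma_eps` defaults to 5% and `sigma_b` to 8% of the
#' outcome amplitude.  The age surface is quadratic with a turning point at
#' 48 years; the speed surface is monotone in speed with its largest effect
#' early in the gait cycle.
#'
#' @param outcome outcome name from [gait_outcomes()].
#' @param sigma_eps,sigma_b optional overrides, in outcome units.
#' @param amplitude optional override of the outcome amplitude.
#' @return an object of class `simulation_truth`.
#' @export
default_truth <- function(outcome = "hip_sagittal_angle", sigma_eps = NULL,
                          sigma_b = NULL, amplitude = NULL) {
  reg <- gait_outcomes()
  idx <- match(outcome, reg$outcome)
  if (is.na(idx)) stop_invalid("unknown outcome: ", outcome)
  fam_amp <- c(angle = 30, moment = 1.5, power = 3)
  amp <- amplitude %||% switch(reg$outcome[idx],
    grf_vertical = 10, grf_ap = 2,
    unname(fam_amp[reg$family[idx]])
  )
  params <- list(
    outcome = outcome, units = reg$units[idx], amplitude = amp,
    phase = 0.03 * ((idx - 1L) %% 5L),
    beta_sex = 0.05 * amp, beta_side = 0.02 * amp,
    sigma_eps = sigma_eps %||% (0.05 * amp),
    sigma_b = sigma_b %||% (0.08 * amp),
    ranges = list(
      age = c(3, 91), speed = c(0.3, 2.6), cadence = c(40, 220),
      height = c(0.85, 2.05), mass = c(10, 120)
    )
  )
  build_truth(params)
}

# Assemble closures + centring curves from a plain parameter list (the form
# serialised to JSON).
build_truth <- function(params) {
  amp <- params$amplitude
  ph <- params$phase
  s_of <- function(t) t / 100
  beta0 <- function(t) {
    s <- s_of(t) + ph
    amp * (0.9 * exp(-((s - 0.25) / 0.15)^2) -
             0.8 * exp(-((s - 0.72) / 0.12)^2) + 0.1)
  }
  # raw (uncentred) surfaces: g(x) * h(t)
  raw <- list(
    age = function(x, t) {
      0.25 * amp * (1 - ((x - 48) / 45)^2) * exp(-((s_of(t) - 0.3) / 0.25)^2)
    },
    speed = function(x, t) {
      0.35 * amp * log(x / 1.2) * (exp(-(s_of(t) / 0.25)^2) + 0.3)
    },
    cadence = function(x, t) {
      0.08 * amp * ((x - 115) / 40) * sin(2 * pi * s_of(t))
    },
    height = function(x, t) {
      0.08 * amp * ((x - 1.5) / 0.4) * cos(2 * pi * s_of(t))
    },
    mass = function(x, t) {
      0.06 * amp * ((x - 55) / 40) * (s_of(t) - 0.5)
    }
  )
  t_grid <- gait_t_grid()
  centred <- lapply(names(raw), function(nm) {
    f <- raw[[nm]]
    rng <- params$ranges[[nm]]
    xg <- seq(rng[1], rng[2], length.out = 201L)
    centre <- vapply(t_grid, function(t) mean(f(xg, t)), numeric(1))
    force(f); force(rng); force(centre)
    function(x, t) {
      if (any(x < rng[1] - 1e-9) || any(x > rng[2] + 1e-9)) {
        stop_invalid("covariate `", nm, "` outside truth range [",
                     rng[1], ", ", rng[2], "]")
      }
      f(x, t) - centre[match(t, t_grid)]
    }
  })
  names(centred) <- names(raw)

  # subject intercept basis: smooth 6-dim cubic spline, scaled so the pooled
  # curve SD equals sigma_b
  bspec <- basis_spec(6L, 3L, domain = c(0, 99))
  Bsub <- bspline_basis(t_grid, bspec)
  coef_sd <- params$sigma_b / sqrt(mean(rowSums(Bsub^2)))

  structure(
    list(
      params = params,
      beta0 = beta0,
      f = centred,
      beta_sex = params$beta_sex, beta_side = params$beta_side,
      sigma_b = params$sigma_b, sigma_eps = params$sigma_eps,
      subject_basis = Bsub, subject_coef_sd = coef_sd,
      subject_intercepts = list()
    ),
    class = "simulation_truth"
  )
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth for", x$params$outcome,
      sprintf("(amplitude %.3g %s, sigma_eps %.3g, sigma_b %.3g)\n",
              x$params$amplitude, x$params$units, x$sigma_eps, x$sigma_b))
  invisible(x)
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647)
}

#' Sample a synthetic lifespan cohort of covariates
#'
#' Draws `n_subjects` participants with ages uniform on the configured range
#' (default 3--91 years), sex-specific adult anthropometry with an
#' age-dependent growth curve below 18 years, and an age-dependent
#' comfortable walking speed.  Each subject contributes exactly three
#' observations: slow (70% of comfortable), comfortable and fast (130% of
#' comfortable) walking, the within-subject speed ratios being exact.
#' Cadence is recomputed per observation from speed, height and a
#' person-specific step-length preference (step length about
#' 0.41 x height x pref, pref ~ N(1, 0.07)), so it is positively associated
#' with speed while still carrying subject-level variation of its own; side
#' alternates across observations.
#'
#' @param n_subjects number of participants (>= 1).
#' @param seed integer seed; identical `(n_subjects, seed, config)` give an
#'   identical table.
#' @param config optional list; honours `age_range` (default `c(3, 91)`).
#' @return data.frame with one row per observation and columns `subject_id`,
#'   `obs_id`, `sex`, `age`, `speed`, `mass`, `height`, `cadence`, `side`,
#'   `speed_condition`.
#' @export
sample_covariates <- function(n_subjects, seed = 1L, config = list()) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 1L)
  age_range <- config$age_range %||% c(3, 91)
  with_seed(seed, {
    sex <- sample(c("male", "female"), n_subjects, replace = TRUE)
    age <- stats::runif(n_subjects, age_range[1], age_range[2])
    h_adult <- stats::rnorm(n_subjects, ifelse(sex == "male", 1.77, 1.64), 0.06)
    frac <- pmin(1, (age / 18)^0.6)
    height <- 0.5 + frac * (h_adult - 0.5)
    bmi <- 15.5 + 8.5 * stats::plogis((age - 14) / 4) + stats::rnorm(n_subjects, 0, 1.2)
    mass <- pmin(pmax(bmi * height^2, 11), 115)
    v_comf <- 1.40 - 0.012 * pmax(age - 60, 0) - 0.8 * exp(-age / 5) +
      stats::rnorm(n_subjects, 0, 0.08)
    v_comf <- pmin(pmax(v_comf, 0.45), 1.9)

    # person-specific step-length preference (~7% SD) so that cadence carries
    # variation that is not fully determined by speed and height
    step_pref <- stats::rnorm(n_subjects, 1, 0.07)

    cond <- c("slow", "comfortable", "fast")
    mult <- c(slow = 0.7, comfortable = 1.0, fast = 1.3)
    i <- rep(seq_len(n_subjects), each = 3L)
    j <- rep(1:3, times = n_subjects)
    speed <- v_comf[i] * mult[cond[j]]
    cadence <- 60 * speed / (0.414 * height[i] * step_pref[i]) +
      stats::rnorm(length(i), 0, 2)
    cadence <- pmin(pmax(cadence, 41), 219)
    side <- ifelse((i + j) %% 2L == 0L, "left", "right")
    out <- data.frame(
      subject_id = sprintf("S%04d", i),
      obs_id = sprintf("S%04d_%s_%s", i, cond[j], side),
      sex = sex[i], age = age[i], speed = as.numeric(speed),
      mass = mass[i], height = height[i], cadence = as.numeric(cadence),
      side = side, speed_condition = cond[j],
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Evaluate the true mean waveform of one observation
#'
#' Sums the generating model's terms on the 100-point gait-cycle grid:
#' `beta0(t) + sum_f f(x, t) + beta_sex I(female) + beta_side I(right)`,
#' plus the subject's smooth random intercept `b_i(t)` when
#' `include_subject = TRUE` (requires that the subject's intercept has been
#' drawn, e.g. by [generate_cohort()]).
#'
#' @param rec one covariate record: a one-row data.frame or named list with
#'   the fields of [sample_covariates()].
#' @param truth a `simulation_truth`.
#' @param include_subject add the subject intercept curve `b_i(t)`.
#' @return numeric vector of 100 values.
#' @export
true_mean_curve <- function(rec, truth, include_subject = FALSE) {
  stopifnot(inherits(truth, "simulation_truth"))
  rec <- as.list(rec)
  t_grid <- gait_t_grid()
  mu <- truth$beta0(t_grid)
  for (nm in names(truth$f)) {
    x <- rec[[covariate_field(nm)]]
    if (is.null(x) || !is.finite(x)) stop_invalid("missing covariate: ", nm)
    mu <- mu + truth$f[[nm]](x, t_grid)
  }
  mu <- mu + truth$beta_sex * as.numeric(rec$sex == "female") +
    truth$beta_side * as.numeric(rec$side == "right")
  if (include_subject) {
    b <- truth$subject_intercepts[[rec$subject_id]]
    if (is.null(b)) {
      stop_invalid("no subject intercept drawn for ", rec$subject_id,
                   "; run generate_cohort() first")
    }
    mu <- mu + as.numeric(truth$subject_basis %*% b)
  }
  mu
}

covariate_field <- function(nm) {
  switch(nm, age = "age", speed = "speed", cadence = "cadence",
         height = "height", mass = "mass", nm)
}

#' Generate a synthetic gait cohort with known ground truth
#'
#' Samples covariates, draws one smooth random-intercept curve per subject
#' (and per outcome), and emits noisy observation waveforms
#' `y = true mean + b_i(t) + N(0, sigma_eps^2)` i.i.d. per grid point, in
#' the long format consumed by [fit_fosr()].
#'
#' @param n_subjects number of participants.
#' @param seed integer seed controlling covariates, subject intercepts and
#'   noise.
#' @param truth a `simulation_truth`, or a list of them (one per outcome).
#' @param config passed to [sample_covariates()].
#' @return list with `covariates` (data.frame), `curves` (long data.frame
#'   with columns `subject_id`, `obs_id`, `outcome`, `side`,
#'   `speed_condition`, `t`, `value`) and `truth` (list per outcome, with
#'   the drawn `subject_intercepts` filled in).
#' @export
generate_cohort <- function(n_subjects, seed = 1L,
                            truth = default_truth(), config = list()) {
  if (inherits(truth, "simulation_truth")) truth <- list(truth)
  names(truth) <- vapply(truth, function(tr) tr$params$outcome, character(1))
  covariates <- sample_covariates(n_subjects, seed, config)
  subjects <- unique(covariates$subject_id)
  t_grid <- gait_t_grid()
  curve_list <- vector("list", length(truth))
  for (k in seq_along(truth)) {
    tr <- truth[[k]]
    with_seed(derive_seed(seed, k), {
      ints <- lapply(subjects, function(s) {
        stats::rnorm(ncol(tr$subject_basis), 0, tr$subject_coef_sd)
      })
      names(ints) <- subjects
      tr$subject_intercepts <- ints
      vals <- lapply(seq_len(nrow(covariates)), function(r) {
        mu <- true_mean_curve(covariates[r, ], tr, include_subject = TRUE)
        mu + stats::rnorm(length(t_grid), 0, tr$sigma_eps)
      })
      truth[[k]] <- tr
      curve_list[[k]] <- data.frame(
        subject_id = rep(covariates$subject_id, each = length(t_grid)),
        obs_id = rep(covariates$obs_id, each = length(t_grid)),
        outcome = tr$params$outcome,
        side = rep(covariates$side, each = length(t_grid)),
        speed_condition = rep(covariates$speed_condition, each = length(t_grid)),
        t = rep(t_grid, times = nrow(covariates)),
        value = unlist(vals),
        stringsAsFactors = FALSE
      )
    })
  }
  list(
    covariates = covariates,
    curves = do.call(rbind, curve_list),
    truth = truth
  )
}

#' Serialise simulation truth parameters to JSON
#'
#' Writes the plain parameters of a `simulation_truth` (amplitudes, scalar
#' effects, noise SDs, covariate ranges) so that tests and downstream tools
#' can introspect the generating model; [read_truth()] rebuilds the full
#' truth object (closures included) from the file.
#'
#' @param truth a `simulation_truth`.
#' @param path output JSON path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  jsonlite::write_json(truth$params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  params <- jsonlite::read_json(path, simplifyVector = TRUE)
  params$ranges <- lapply(params$ranges, as.numeric)
  build_truth(params)
}
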