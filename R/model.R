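#' Model configuration for the function-on-scalar fit
#'
#' Defaults follow standard penalized-spline practice: cubic B-splines with
#' second-order difference penalties, 20 basis functions for pure-time terms
#' (the time-varying intercept and the subject random-intercept curves) and
#' 8 x 8 tensor products for each covariate-by-time surface.  Covariate
#' domains are taken from the observed training range extended by 1% on each
#' side so that prediction at the boundary of the training range is allowed.
#'
#' @param n_basis_t basis dimension for pure-time terms.
#' @param n_basis_x marginal basis dimension of tensor smooths (covariate
#'   direction); the time margin of tensor smooths uses `n_basis_tensor_t`.
#' @param n_basis_tensor_t time-margin dimension of tensor smooths.
#' @param degree spline degree.
#' @param penalty_order difference-penalty order.
#' @param smooth_covariates continuous covariates entering as
#'   covariate-by-time smooths.
#' @param include_random include per-subject functional random intercepts.
#' @param smoothing smoothing-parameter selection criterion, `"REML"`
#'   (default) or `"GCV"`.
#' @param lambda optional fixed named vector of smoothing parameters (one
#'   per penalty; see [select_smoothing()] for the naming scheme).  When
#'   supplied, data-driven selection is skipped — useful for reproducible
#'   tests.
#' @param domain_extend fractional extension of observed covariate ranges.
#' @param optim_control list passed to [stats::optim()] during smoothing
#'   selection.
#' @return list of class `fosr_config`.
#' @export
fosr_config <- function(n_basis_t = 20L, n_basis_x = 8L, n_basis_tensor_t = 8L,
                        degree = 3L, penalty_order = 2L,
                        smooth_covariates = c("age", "speed", "cadence",
                                              "height", "mass"),
                        include_random = TRUE,
                        smoothing = c("REML", "GCV"),
                        lambda = NULL, domain_extend = 0.01,
                        optim_control = list()) {
  smoothing <- match.arg(smoothing)
  cfg <- list(
    n_basis_t = check_count(n_basis_t, "n_basis_t", 4L),
    n_basis_x = check_count(n_basis_x, "n_basis_x", 4L),
    n_basis_tensor_t = check_count(n_basis_tensor_t, "n_basis_tensor_t", 4L),
    degree = check_count(degree, "degree", 1L),
    penalty_order = check_count(penalty_order, "penalty_order", 1L),
    smooth_covariates = smooth_covariates,
    include_random = isTRUE(include_random),
    smoothing = smoothing,
    lambda = lambda,
    domain_extend = check_scalar_number(domain_extend, "domain_extend", 0),
    optim_control = optim_control
  )
  class(cfg) <- "fosr_config"
  cfg
}

required_covariate_fields <- function() {
  c("subject_id", "sex", "age", "speed", "mass", "height", "cadence", "side")
}

validate_covariates <- function(covariates) {
  miss <- setdiff(required_covariate_fields(), names(covariates))
  if (length(miss)) {
    stop_invalid("covariate table is missing field(s): ",
                 paste(miss, collapse = ", "))
  }
  for (f in c("age", "speed", "mass", "height", "cadence")) {
    if (anyNA(covariates[[f]]) || !all(is.finite(covariates[[f]]))) {
      stop_invalid("covariate `", f, "` contains missing or non-finite values")
    }
    if (f != "age" && any(covariates[[f]] <= 0)) {
      stop_invalid("covariate `", f, "` must be strictly positive")
    }
  }
  bad_sex <- !covariates$sex %in% c("male", "female")
  if (any(bad_sex)) stop_invalid("covariate `sex` must be 'male' or 'female'")
  if (!all(covariates$side %in% c("left", "right"))) {
    stop_invalid("covariate `side` must be 'left' or 'right'")
  }
  invisible(covariates)
}

#' Assemble the function-on-scalar design in long form
#'
#' Stacks every observation's 100 grid points into one response-length design
#' with named column blocks: the time-varying intercept, one sum-to-zero
#' constrained tensor-product smooth per continuous covariate, time-constant
#' indicator columns for sex (male = 0, female = 1) and side (left = 0,
#' right = 1), and optionally one penalized spline-in-time block per subject
#' for the functional random intercepts.  Fixed-effect columns precede the
#' random-effect columns; block column ranges are disjoint and contiguous.
#'
#' @param covariates covariate table, one row per observation curve.
#' @param t_grid evaluation grid (default the 100-point gait cycle).
#' @param config a [fosr_config()].
#' @param ranges optional precomputed covariate domains (named list of
#'   length-2 vectors); defaults to the observed range extended by
#'   `config$domain_extend`.
#' @return an object of class `fosr_design`.
#' @export
assemble_design <- function(covariates, t_grid = gait_t_grid(),
                            config = fosr_config(), ranges = NULL) {
  validate_covariates(covariates)
  n_obs <- nrow(covariates)
  n_t <- length(t_grid)
  N <- n_obs * n_t

  if (is.null(ranges)) {
    ranges <- lapply(config$smooth_covariates, function(nm) {
      r <- range(covariates[[nm]])
      w <- diff(r) * config$domain_extend
      if (w <= 0) stop_invalid("covariate `", nm, "` is constant; cannot build a smooth")
      c(r[1] - w, r[2] + w)
    })
    names(ranges) <- config$smooth_covariates
  }

  spec_t_main <- basis_spec(config$n_basis_t, config$degree,
                            domain = range(t_grid))
  spec_t_tensor <- basis_spec(config$n_basis_tensor_t, config$degree,
                              domain = range(t_grid))
  Bt_main <- bspline_basis(t_grid, spec_t_main)
  Bt_tensor <- bspline_basis(t_grid, spec_t_tensor)
  Pt_main <- difference_penalty(config$n_basis_t, config$penalty_order)$matrix
  Pt_tensor <- difference_penalty(config$n_basis_tensor_t,
                                  config$penalty_order)$matrix
  Px <- difference_penalty(config$n_basis_x, config$penalty_order)$matrix

  rep_obs <- rep(seq_len(n_obs), each = n_t)   # observation of each long row
  rep_t <- rep(seq_len(n_t), times = n_obs)    # grid index of each long row

  Bt_main_sp <- methods::as(Matrix::Matrix(Bt_main, sparse = TRUE), "CsparseMatrix")
  Bt_tensor_sp <- methods::as(Matrix::Matrix(Bt_tensor, sparse = TRUE), "CsparseMatrix")
  Bt_main_long <- Bt_main_sp[rep_t, , drop = FALSE]
  Bt_tensor_long <- Bt_tensor_sp[rep_t, , drop = FALSE]

  blocks <- list()
  Xparts <- list()
  col_at <- 0L

  add_block <- function(name, Xb, info) {
    p_b <- ncol(Xb)
    info$cols <- col_at + seq_len(p_b)
    blocks[[name]] <<- info
    Xparts[[name]] <<- Xb
    col_at <<- col_at + p_b
  }

  add_block("intercept", Bt_main_long,
            list(type = "time", spec_t = spec_t_main,
                 penalties = list(t = Pt_main)))

  spec_x_list <- list()
  for (nm in config$smooth_covariates) {
    spec_x <- basis_spec(config$n_basis_x, config$degree, domain = ranges[[nm]])
    spec_x_list[[nm]] <- spec_x
    Bx <- bspline_basis(covariates[[nm]], spec_x)
    m <- colMeans(Bx)
    qrm <- qr(matrix(m, ncol = 1L))
    Zx <- qr.Q(qrm, complete = TRUE)[, -1L, drop = FALSE]
    Bxc <- Bx %*% Zx
    Bxc_long <- methods::as(Matrix::Matrix(Bxc, sparse = TRUE),
                            "CsparseMatrix")[rep_obs, , drop = FALSE]
    Xb <- row_kronecker(Bxc_long, Bt_tensor_long)
    add_block(nm, Xb, list(
      type = "tensor", x_name = nm, spec_x = spec_x, spec_t = spec_t_tensor,
      transform = Zx,
      penalties = list(
        x = kronecker(crossprod(Zx, Px %*% Zx), diag(ncol(Bt_tensor))),
        t = kronecker(diag(ncol(Zx)), Pt_tensor)
      )
    ))
  }

  sex_col <- Matrix::Matrix(as.numeric(covariates$sex == "female")[rep_obs],
                            ncol = 1L, sparse = TRUE)
  side_col <- Matrix::Matrix(as.numeric(covariates$side == "right")[rep_obs],
                             ncol = 1L, sparse = TRUE)
  add_block("sex", sex_col, list(type = "scalar", penalties = list()))
  add_block("side", side_col, list(type = "scalar", penalties = list()))

  n_fixed <- col_at
  subjects <- unique(covariates$subject_id)

  if (config$include_random) {
    K <- config$n_basis_t
    subj_of_obs <- match(covariates$subject_id, subjects)
    trip <- Matrix::summary(Bt_main_long)  # i (long row), j (basis col), x
    subj_row <- subj_of_obs[rep_obs]
    Xr <- Matrix::sparseMatrix(
      i = trip$i,
      j = (subj_row[trip$i] - 1L) * K + trip$j,
      x = trip$x,
      dims = c(N, length(subjects) * K)
    )
    add_block("subject", Xr, list(
      type = "random", spec_t = spec_t_main, subjects = subjects,
      penalties = list(ridge = "identity")
    ))
  }

  X <- do.call(cbind, Xparts)
  structure(
    list(
      X = methods::as(X, "CsparseMatrix"), blocks = blocks,
      n_obs = n_obs, n_fixed = n_fixed, p = ncol(X),
      t_grid = t_grid, ranges = ranges, subjects = subjects,
      config = config,
      spec_t_main = spec_t_main, spec_t_tensor = spec_t_tensor
    ),
    class = "fosr_design"
  )
}

# ---- penalty bookkeeping ---------------------------------------------------

# One entry per smoothing parameter: embedded sparse p x p matrix plus the
# small within-block matrix (for pseudo-determinants and matrix square roots).
penalty_entries <- function(design) {
  p <- design$p
  entries <- list()
  for (nm in names(design$blocks)) {
    blk <- design$blocks[[nm]]
    if (blk$type == "random") {
      entries[[paste0(nm)]] <- list(
        block = nm, cols = blk$cols, small = NULL, ridge = TRUE
      )
    } else {
      for (pn in names(blk$penalties)) {
        entries[[paste(nm, pn, sep = "_")]] <- list(
          block = nm, cols = blk$cols,
          small = blk$penalties[[pn]], ridge = FALSE
        )
      }
    }
  }
  entries
}

embed_penalty <- function(entry, p) {
  if (entry$ridge) {
    Matrix::sparseMatrix(i = entry$cols, j = entry$cols,
                         x = rep(1, length(entry$cols)), dims = c(p, p))
  } else {
    Ssm <- methods::as(methods::as(Matrix::Matrix(entry$small, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix")
    trip <- Matrix::summary(Ssm)
    Matrix::sparseMatrix(i = entry$cols[trip$i], j = entry$cols[trip$j],
                         x = trip$x, dims = c(p, p))
  }
}

# Eigen decompositions of the within-block penalty sums are needed per
# lambda; group the entries by block once.
penalty_groups <- function(entries) {
  split(seq_along(entries), vapply(entries, `[[`, "", "block"))
}

# log pseudo-determinant and rank of S(lambda) restricted to one block
block_logdet <- function(entries, idx, lambda, rank_cache = NULL) {
  first <- entries[[idx[1]]]
  if (first$ridge) {
    n_cols <- length(first$cols)
    return(list(logdet = n_cols * log(lambda[idx[1]]), rank = n_cols))
  }
  Ssum <- Reduce(`+`, Map(function(i) lambda[i] * entries[[i]]$small, idx))
  ev <- eigen(Ssum, symmetric = TRUE, only.values = TRUE)$values
  r <- rank_cache %||% sum(ev > max(ev) * 1e-9)
  list(logdet = sum(log(ev[seq_len(r)])), rank = r)
}

# matrix square root R of S(lambda) over one block (S = R R')
block_root <- function(entries, idx, lambda) {
  first <- entries[[idx[1]]]
  if (first$ridge) {
    n_cols <- length(first$cols)
    return(list(cols = first$cols,
                R = diag(sqrt(lambda[idx[1]]), n_cols)))
  }
  Ssum <- Reduce(`+`, Map(function(i) lambda[i] * entries[[i]]$small, idx))
  ed <- eigen(Ssum, symmetric = TRUE)
  keep <- ed$values > max(ed$values) * 1e-9
  list(cols = first$cols,
       R = ed$vectors[, keep, drop = FALSE] %*% diag(sqrt(ed$values[keep]),
                                                     sum(keep)))
}

# ---- penalized least squares core ------------------------------------------

# Precomputed pieces shared across lambda evaluations.
fosr_workspace <- function(design, y) {
  X <- design$X
  entries <- penalty_entries(design)
  S_embedded <- lapply(entries, embed_penalty, p = design$p)
  XtX <- Matrix::forceSymmetric(Matrix::crossprod(X))
  ws <- list(
    X = X, y = y, XtX = XtX, Xty = as.numeric(Matrix::crossprod(X, y)),
    yty = sum(y^2), N = length(y), p = design$p,
    entries = entries, S_embedded = S_embedded,
    groups = penalty_groups(entries)
  )
  # fixed block ranks (lambda-independent); evaluate once at lambda = 1
  ones <- rep(1, length(entries))
  names(ones) <- names(entries)
  ws$block_ranks <- lapply(ws$groups, function(idx) {
    block_logdet(entries, idx, ones)$rank
  })
  ws$rank_S <- sum(unlist(ws$block_ranks))
  ws$null_dim <- ws$p - ws$rank_S
  # symbolic factorisation reused across lambda values
  A1 <- ws$XtX + Reduce(`+`, S_embedded)
  ws$chol <- Matrix::Cholesky(Matrix::forceSymmetric(A1), LDL = FALSE,
                              perm = TRUE, super = TRUE)
  ws
}

penalized_solve <- function(ws, lambda) {
  S <- Reduce(`+`, Map(function(Sk, lk) lk * Sk, ws$S_embedded, lambda))
  A <- Matrix::forceSymmetric(ws$XtX + S)
  ch <- Matrix::update(ws$chol, A)
  beta <- as.numeric(Matrix::solve(ch, ws$Xty, system = "A"))
  rss_pen <- max(ws$yty - sum(beta * ws$Xty), .Machine$double.eps)
  list(beta = beta, chol = ch, A = A, S = S, rss_pen = rss_pen,
       logdet_A = as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                                 sqrt = FALSE)$modulus))
}

logdet_S_plus <- function(ws, lambda) {
  sum(vapply(names(ws$groups), function(g) {
    block_logdet(ws$entries, ws$groups[[g]], lambda,
                 rank_cache = ws$block_ranks[[g]])$logdet
  }, numeric(1)))
}

# effective degrees of freedom tr(A^-1 XtX) = p - tr(A^-1 S) via the
# Frobenius-norm trick on a blockwise matrix square root of S
edf_from_fit <- function(ws, lambda, sol) {
  roots <- lapply(names(ws$groups), function(g) {
    block_root(ws$entries, ws$groups[[g]], lambda)
  })
  total_rank <- sum(vapply(roots, function(r) ncol(r$R), numeric(1)))
  if (total_rank == 0L) return(ws$p)
  Rbig <- Matrix::sparseMatrix(
    i = unlist(lapply(roots, function(r) rep(r$cols, times = ncol(r$R)))),
    j = unlist(local({
      off <- 0L
      lapply(roots, function(r) {
        jj <- rep(off + seq_len(ncol(r$R)), each = nrow(r$R))
        off <<- off + ncol(r$R)
        jj
      })
    })),
    x = unlist(lapply(roots, function(r) as.numeric(r$R))),
    dims = c(ws$p, total_rank)
  )
  W <- Matrix::solve(sol$chol,
                     Matrix::solve(sol$chol, Rbig, system = "P"),
                     system = "L")
  ws$p - sum(W@x^2)
}

reml_score <- function(ws, lambda) {
  sol <- penalized_solve(ws, lambda)
  (ws$N - ws$null_dim) * log(sol$rss_pen) + sol$logdet_A -
    logdet_S_plus(ws, lambda)
}

gcv_score <- function(ws, lambda) {
  sol <- penalized_solve(ws, lambda)
  edf <- edf_from_fit(ws, lambda, sol)
  rss <- sum((ws$y - as.numeric(ws$X %*% sol$beta))^2)
  ws$N * rss / (ws$N - edf)^2
}

#' Select smoothing parameters by REML or GCV
#'
#' Optimizes the restricted-likelihood score (with the residual variance
#' profiled out) or the generalized cross-validation score over the log
#' smoothing parameters with Nelder-Mead, starting from a scale-matched
#' initial guess.  One smoothing parameter is selected per penalty: the
#' time-varying intercept has one (`intercept_t`), each covariate-by-time
#' tensor smooth has two (`<name>_x`, `<name>_t`) and the subject
#' random-intercept block has one shared ridge parameter (`subject`).
#'
#' @param design an [assemble_design()] result.
#' @param response stacked response vector (length `n_obs * length(t_grid)`).
#' @param method `"REML"` or `"GCV"`.
#' @param control passed to [stats::optim()].
#' @return list with `lambda` (named vector), `criterion`, `method`,
#'   `convergence` and the optimizer's evaluation `trace`.
#' @export
select_smoothing <- function(design, response, method = c("REML", "GCV"),
                             control = list()) {
  method <- match.arg(method)
  ws <- fosr_workspace(design, response)
  entries <- ws$entries
  # scale-matched initial lambda: tr(XtX_block) / tr(P_k)
  dXtX <- Matrix::diag(ws$XtX)
  lam0 <- vapply(entries, function(e) {
    trS <- if (e$ridge) length(e$cols) else sum(diag(e$small))
    max(sum(dXtX[e$cols]) / trS, 1e-4)
  }, numeric(1))
  score_fun <- if (method == "REML") reml_score else gcv_score
  trace_env <- new.env(parent = emptyenv())
  trace_env$log <- list()
  obj <- function(logl) {
    # keep lambdas inside a numerically safe window
    if (any(!is.finite(logl)) || any(abs(logl) > 50)) return(1e300)
    val <- suppressWarnings(score_fun(ws, exp(logl)))
    trace_env$log[[length(trace_env$log) + 1L]] <-
      c(score = val, stats::setNames(logl, names(lam0)))
    if (!is.finite(val)) return(1e300)
    val
  }
  ctrl <- utils::modifyList(list(maxit = 750L, reltol = 1e-7), control)
  opt <- stats::optim(log(lam0), obj, method = "Nelder-Mead", control = ctrl)
  # 1 = iteration limit, 10 = simplex degeneracy: both leave a usable
  # optimum; anything else aborts with the evaluation trace attached
  if (!opt$convergence %in% c(0L, 1L, 10L)) {
    cond <- simpleError(paste0("smoothing optimizer failed to converge (code ",
                               opt$convergence, ")"))
    cond$trace <- trace_env$log
    stop(cond)
  }
  list(
    lambda = stats::setNames(exp(opt$par), names(lam0)),
    criterion = opt$value, method = method,
    convergence = opt$convergence, trace = trace_env$log
  )
}

# ---- the full fit ----------------------------------------------------------

align_response <- function(curves, covariates, outcome, t_grid) {
  if (!all(c("obs_id", "t", "value", "outcome") %in% names(curves))) {
    stop_invalid("curves must be a long table with columns obs_id, outcome, t, value")
  }
  cu <- curves[curves$outcome == outcome, , drop = FALSE]
  if (nrow(cu) == 0L) stop_invalid("no curves found for outcome `", outcome, "`")
  key <- paste(cu$obs_id, cu$t)
  want <- paste(rep(covariates$obs_id, each = length(t_grid)),
                rep(t_grid, times = nrow(covariates)))
  idx <- match(want, key)
  if (anyNA(idx)) {
    missing_obs <- unique(rep(covariates$obs_id,
                              each = length(t_grid))[is.na(idx)])
    stop_invalid("curves and covariates do not match for outcome `", outcome,
                 "`: no complete curve for observation(s) ",
                 paste(utils::head(missing_obs, 3), collapse = ", "))
  }
  cu$value[idx]
}

#' Fit a function-on-scalar regression model to one gait outcome
#'
#' Minimizes the penalized least squares criterion
#' \eqn{\|y - X\beta\|^2 + \sum_k \lambda_k \beta^\top P_k \beta}
#' over the stacked waveform response, with smoothing parameters chosen by
#' REML (default) or GCV unless fixed in the configuration.  The returned
#' fit carries per-block coefficients, the Bayesian coefficient covariance of
#' the fixed-effect block \eqn{\hat\sigma^2 (X^\top X + S)^{-1}}, the
#' residual variance estimate, and the training metadata needed for
#' prediction and guard rails (covariate ranges, quantiles, subject ids).
#'
#' @param curves long-format curve table (see [read_curves()]).
#' @param covariates covariate table, one row per observation curve.
#' @param outcome outcome to fit; may be omitted when `curves` contains a
#'   single outcome.
#' @param config a [fosr_config()].
#' @param t_grid evaluation grid.
#' @param ranges optional covariate domains (named list of length-2 vectors),
#'   e.g. from a larger cohort than the training subset; defaults to the
#'   observed training range extended by `config$domain_extend`.
#' @return an object of class `fosr_fit`.
#' @export
fit_fosr <- function(curves, covariates, outcome = NULL,
                     config = fosr_config(), t_grid = gait_t_grid(),
                     ranges = NULL) {
  validate_covariates(covariates)
  if (is.null(covariates$obs_id)) {
    covariates$obs_id <- paste(covariates$subject_id,
                               covariates$speed_condition %||% seq_len(nrow(covariates)),
                               covariates$side, sep = "_")
  }
  if (is.null(outcome)) {
    outs <- unique(curves$outcome)
    if (length(outs) != 1L) {
      stop_invalid("curves contain ", length(outs),
                   " outcomes; specify `outcome` (one model per outcome)")
    }
    outcome <- outs
  }
  if (!all(unique(curves$subject_id) %in% covariates$subject_id)) {
    stop_invalid("curves contain subject ids absent from the covariate table")
  }
  y <- align_response(curves, covariates, outcome, t_grid)
  design <- assemble_design(covariates, t_grid, config, ranges)
  ws <- fosr_workspace(design, y)

  if (!is.null(config$lambda)) {
    lambda <- resolve_fixed_lambda(config$lambda, names(ws$entries))
    smoothing_info <- list(method = "fixed", lambda = lambda)
  } else {
    sel <- select_smoothing(design, y, method = config$smoothing,
                            control = config$optim_control)
    lambda <- sel$lambda
    smoothing_info <- sel[c("method", "criterion", "convergence")]
    smoothing_info$lambda <- lambda
  }

  sol <- penalized_solve(ws, lambda)
  edf <- edf_from_fit(ws, lambda, sol)
  sigma2 <- sol$rss_pen / max(ws$N - edf, 1)

  n_fixed <- design$n_fixed
  Ifix <- Matrix::sparseMatrix(i = seq_len(n_fixed), j = seq_len(n_fixed),
                               x = 1, dims = c(ws$p, n_fixed))
  Ainv_fix <- Matrix::solve(sol$chol, Ifix, system = "A")
  Vb_fixed <- sigma2 * as.matrix(Ainv_fix[seq_len(n_fixed), , drop = FALSE])
  Vb_fixed <- (Vb_fixed + t(Vb_fixed)) / 2

  beta <- sol$beta
  coef_blocks <- lapply(design$blocks, function(b) beta[b$cols])

  qprobs <- c(0.25, 0.5, 0.75)
  quantiles <- lapply(config$smooth_covariates, function(nm) {
    stats::quantile(covariates[[nm]], probs = qprobs, names = FALSE, type = 7)
  })
  names(quantiles) <- config$smooth_covariates

  sigma2_b <- if (config$include_random) sigma2 / lambda[["subject"]] else 0

  structure(
    list(
      outcome = outcome, units = tryCatch(outcome_units(outcome),
                                          error = function(e) NA_character_),
      coefficients = beta, coef_blocks = coef_blocks,
      blocks = lapply(design$blocks, function(b) {
        b[setdiff(names(b), character(0))]
      }),
      n_fixed = n_fixed, p = ws$p,
      lambda = lambda, smoothing = smoothing_info,
      Vb_fixed = Vb_fixed, sigma2 = sigma2, sigma2_b = sigma2_b,
      edf = edf, rss_pen = sol$rss_pen,
      t_grid = t_grid, ranges = design$ranges,
      config = config,
      metadata = list(
        n = length(design$subjects), n_obs = design$n_obs,
        subjects = design$subjects,
        quantiles = quantiles, quantile_type = 7L,
        deployment = FALSE,
        package_version = as.character(utils::packageVersion("gaitnorm"))
      )
    ),
    class = "fosr_fit"
  )
}

resolve_fixed_lambda <- function(lambda, entry_names) {
  if (is.null(names(lambda))) {
    if (length(lambda) == 1L) {
      lambda <- stats::setNames(rep(lambda, length(entry_names)), entry_names)
    } else if (length(lambda) == length(entry_names)) {
      names(lambda) <- entry_names
    } else {
      stop_invalid("fixed `lambda` must be length 1 or name every penalty: ",
                   paste(entry_names, collapse = ", "))
    }
  } else {
    miss <- setdiff(entry_names, names(lambda))
    if (length(miss)) {
      stop_invalid("fixed `lambda` is missing penalties: ",
                   paste(miss, collapse = ", "))
    }
    lambda <- lambda[entry_names]
  }
  if (any(!is.finite(lambda) | lambda < 0)) {
    stop_invalid("`lambda` must be finite and >= 0")
  }
  lambda
}

#' Refit on the full data set for deployment
#'
#' Identical pipeline to [fit_fosr()], but the resulting fit is flagged as a
#' deployment fit: [evaluate_model()] refuses to score it against its own
#' training subjects unless explicitly overridden.
#'
#' @inheritParams fit_fosr
#' @return an `fosr_fit` with `metadata$deployment = TRUE`.
#' @export
refit_full <- function(curves, covariates, outcome = NULL,
                       config = fosr_config(), t_grid = gait_t_grid(),
                       ranges = NULL) {
  fit <- fit_fosr(curves, covariates, outcome, config, t_grid, ranges)
  fit$metadata$deployment <- TRUE
  fit
}

#' @export
print.fosr_fit <- function(x, ...) {
  cat("Function-on-scalar fit for outcome `", x$outcome, "` (",
      x$units, ")\n", sep = "")
  cat(sprintf("  %d subjects, %d observation curves, %d grid points\n",
              x$metadata$n, x$metadata$n_obs, length(x$t_grid)))
  cat(sprintf("  %d coefficients (%d fixed), edf %.1f, sigma^2 %.4g\n",
              x$p, x$n_fixed, x$edf, x$sigma2))
  cat("  smoothing:", x$smoothing$method, "| lambda:",
      paste(sprintf("%s=%.3g", names(x$lambda), x$lambda), collapse = ", "),
      "\n")
  if (isTRUE(x$metadata$deployment)) cat("  deployment fit (full data)\n")
  invisible(x)
}
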