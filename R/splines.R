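#' B-spline basis specification
#'
#' Describes a marginal B-spline basis with equally spaced interior knots over
#' a closed domain.  Cubic splines (`degree = 3`) are the default throughout
#' the package; the basis dimension must exceed the degree so that at least
#' one B-spline spans the domain.
#'
#' @param n_basis number of basis functions (>= 4 for a cubic basis;
#'   must satisfy `n_basis > degree`).
#' @param degree polynomial degree of the spline pieces (default 3).
#' @param domain numeric length-2 vector, the closed evaluation interval.
#' @return an object of class `basis_spec`.
#' @export
basis_spec <- function(n_basis, degree = 3L, domain = c(0, 1)) {
  n_basis <- check_count(n_basis, "n_basis", min = 1L)
  degree <- check_count(degree, "degree", min = 0L)
  if (n_basis <= degree) stop_invalid("`n_basis` must be > `degree`")
  if (!is.numeric(domain) || length(domain) != 2L || !all(is.finite(domain)) ||
      domain[2] <= domain[1]) {
    stop_invalid("`domain` must be a non-degenerate closed interval c(a, b)")
  }
  structure(
    list(n_basis = n_basis, degree = degree, domain = as.numeric(domain)),
    class = "basis_spec"
  )
}

spec_knots <- function(spec) {
  ord <- spec$degree + 1L
  n_interior <- spec$n_basis - ord
  a <- spec$domain[1]
  b <- spec$domain[2]
  interior <- if (n_interior > 0L) {
    seq(a, b, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  } else {
    numeric(0)
  }
  c(rep(a, ord), interior, rep(b, ord))
}

#' Evaluate a B-spline basis on a grid
#'
#' Rows form a partition of unity (they sum to one) and all entries are
#' non-negative; the right domain boundary is included in the support of the
#' last basis function.
#'
#' @param grid numeric vector of evaluation points, all within `spec$domain`.
#' @param spec a [basis_spec()].
#' @return numeric matrix `length(grid) x spec$n_basis`.
#' @export
bspline_basis <- function(grid, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (!is.numeric(grid) || !all(is.finite(grid))) {
    stop_invalid("`grid` must be finite numeric")
  }
  a <- spec$domain[1]
  b <- spec$domain[2]
  out <- which(grid < a | grid > b)
  if (length(out)) {
    stop_invalid("evaluation point(s) outside basis domain [", a, ", ", b,
                 "]: ", paste(utils::head(signif(grid[out], 6), 3), collapse = ", "))
  }
  knots <- spec_knots(spec)
  # splineDesign drops support at the right boundary for low orders; nudge
  # points sitting exactly on b into the last half-open interval.
  eps <- (b - a) * 1e-12
  g <- ifelse(grid >= b, b - eps, grid)
  B <- splines::splineDesign(knots, g, ord = spec$degree + 1L, outer.ok = FALSE)
  dimnames(B) <- NULL
  B
}

#' Difference penalty matrix
#'
#' Builds the classic P-spline penalty \eqn{P = D^\top D} where `D` is the
#' order-th difference operator acting on adjacent B-spline coefficients.
#' Its null space is spanned by polynomial coefficient sequences up to
#' degree `order - 1`, so `null_space_dim = order`.
#'
#' @param n_basis number of coefficients penalised.
#' @param order difference order (default 2; must be `< n_basis`).
#' @return an object of class `penalty_block` with elements `matrix`
#'   (symmetric PSD), `order` and `null_space_dim`.
#' @export
difference_penalty <- function(n_basis, order = 2L) {
  n_basis <- check_count(n_basis, "n_basis", min = 1L)
  order <- check_count(order, "order", min = 1L)
  if (order >= n_basis) stop_invalid("`order` must be < `n_basis`")
  D <- diff(diag(n_basis), differences = order)
  structure(
    list(matrix = crossprod(D), order = order, null_space_dim = order),
    class = "penalty_block"
  )
}

# Row-wise Kronecker product: row i of the result is A[i, ] %x% B[i, ].
# Column ordering is A-major (B index varies fastest).
row_kronecker <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  if (inherits(A, "Matrix") || inherits(B, "Matrix")) {
    Matrix::t(Matrix::KhatriRao(Matrix::t(A), Matrix::t(B)))
  } else {
    X <- matrix(0, nrow(A), ncol(A) * ncol(B))
    for (j in seq_len(ncol(A))) {
      X[, (j - 1L) * ncol(B) + seq_len(ncol(B))] <- A[, j] * B
    }
    X
  }
}

#' Tensor-product design block for a covariate-by-time smooth
#'
#' Constructs the design matrix of a bivariate smooth f(x, t) as the row-wise
#' Kronecker product of the two marginal B-spline bases, with one
#' Kronecker-extended difference penalty per marginal direction.  Rows are
#' ordered observation-major: for each `x` value all `t` values in sequence.
#'
#' @param x_values covariate value of each observation.
#' @param t_grid evaluation grid in the time direction.
#' @param spec_x,spec_t marginal [basis_spec()]s.
#' @param penalty_order difference-penalty order for both margins.
#' @return list with `design` (`length(x_values)*length(t_grid)` rows,
#'   `n_x * n_t` columns), `penalties` (list of the two Kronecker-extended
#'   PSD matrices, x-direction first) and the marginal bases.
#' @export
tensor_product_block <- function(x_values, t_grid, spec_x, spec_t,
                                 penalty_order = 2L) {
  Bx <- bspline_basis(x_values, spec_x)
  Bt <- bspline_basis(t_grid, spec_t)
  n_x <- ncol(Bx)
  n_t <- ncol(Bt)
  Px <- difference_penalty(n_x, penalty_order)$matrix
  Pt <- difference_penalty(n_t, penalty_order)$matrix
  Bx_long <- Bx[rep(seq_len(nrow(Bx)), each = nrow(Bt)), , drop = FALSE]
  Bt_long <- Bt[rep(seq_len(nrow(Bt)), times = nrow(Bx)), , drop = FALSE]
  list(
    design = row_kronecker(Bx_long, Bt_long),
    penalties = list(
      x = kronecker(Px, diag(n_t)),
      t = kronecker(diag(n_x), Pt)
    ),
    basis_x = Bx, basis_t = Bt
  )
}

#' Absorb sum-to-zero constraints into a design block
#'
#' Reparametrises a penalized design block so that the fitted effect
#' satisfies the linear constraints `C beta = 0`; by default a single
#' constraint built from the column means of `design`, i.e. the fitted
#' effect averages to zero over the training rows.  The block loses one
#' column per constraint and the returned `transform` `Z` (satisfying
#' `C Z = 0`, orthonormal columns) maps constrained coefficients back to the
#' full coefficient space.
#'
#' @param design design matrix of the block.
#' @param penalties list of penalty matrices matching `ncol(design)`.
#' @param constraint optional constraint matrix with `ncol(design)` columns;
#'   defaults to `colMeans(design)` as a single row.
#' @return list `design`, `penalties` (both in the constrained
#'   parametrisation) and `transform`.
#' @export
apply_sum_to_zero_constraint <- function(design, penalties, constraint = NULL) {
  p <- ncol(design)
  if (is.null(constraint)) constraint <- matrix(colMeans(as.matrix(design)), 1L, p)
  constraint <- as.matrix(constraint)
  if (ncol(constraint) != p) {
    stop_invalid("constraint has ", ncol(constraint), " columns, design has ", p)
  }
  for (P in penalties) {
    if (!all(dim(as.matrix(P)) == p)) {
      stop_invalid("penalty dimension does not match design column count")
    }
  }
  qrC <- qr(t(constraint))
  q <- nrow(constraint)
  if (qrC$rank < q) {
    stop_invalid("rank-deficient constraint matrix (rank ", qrC$rank,
                 " < ", q, " rows); remove redundant constraints")
  }
  Z <- qr.Q(qrC, complete = TRUE)[, (q + 1L):p, drop = FALSE]
  list(
    design = design %*% Z,
    penalties = lapply(penalties, function(P) crossprod(Z, as.matrix(P) %*% Z)),
    transform = Z
  )
}
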