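# Independent oracles, kept free of the package's own code paths.

# Cox-de Boor recursion for a single B-spline basis function.
deboor_basis <- function(x, knots, i, degree) {
  if (degree == 0L) {
    # half-open intervals, last interval closed on the right
    upper_ok <- if (knots[i + 1L] >= max(knots)) x <= knots[i + 1L]
                else x < knots[i + 1L]
    return(as.numeric(x >= knots[i] & upper_ok))
  }
  d1 <- knots[i + degree] - knots[i]
  d2 <- knots[i + degree + 1L] - knots[i + 1L]
  a <- if (d1 > 0) (x - knots[i]) / d1 * deboor_basis(x, knots, i, degree - 1L) else 0
  b <- if (d2 > 0) (knots[i + degree + 1L] - x) / d2 *
    deboor_basis(x, knots, i + 1L, degree - 1L) else 0
  a + b
}

deboor_matrix <- function(x, knots, degree) {
  n_basis <- length(knots) - degree - 1L
  sapply(seq_len(n_basis), function(i) deboor_basis(x, knots, i, degree))
}

# Dense closed-form penalized least squares: (X'X + sum lambda_k S_k)^-1 X'y
oracle_penalized <- function(X, y, S_list, lambda) {
  X <- as.matrix(X)
  A <- crossprod(X)
  for (k in seq_along(S_list)) A <- A + lambda[k] * as.matrix(S_list[[k]])
  solve(A, crossprod(X, y))
}

# Brute-force metric oracles by explicit summation loops
oracle_rmse <- function(o, p) {
  acc <- 0
  for (i in seq_along(o)) acc <- acc + (o[i] - p[i])^2
  sqrt(acc / length(o))
}
oracle_relrmse <- function(o, p) {
  oracle_rmse(o, p) / (0.5 * ((max(o) - min(o)) + (max(p) - min(p)))) * 100
}
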