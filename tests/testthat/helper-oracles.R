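# Independent brute-force oracles, deliberately naive: every quantity is
# recomputed from its definition on each pass, with no Gram-matrix
# shortcuts, no standardization and no warm starts.

# Cyclic coordinate descent for
#   1/2 sum_i w_i (y_i - b0 - x_i' b)^2
#     + lambda * sum_j { gamma b_j^2 + (1 - gamma) |b_j| }
# with a free intercept.
oracle_penalized <- function(X, y, w = rep(1, nrow(X)), lambda, gamma = 0,
                             n_pass = 5000L, tol = 1e-12) {
  p <- ncol(X)
  b <- numeric(p)
  b0 <- sum(w * y) / sum(w)
  soft <- function(z, t) sign(z) * max(abs(z) - t, 0)
  for (pass in seq_len(n_pass)) {
    b_old <- b
    for (j in seq_len(p)) {
      r_j <- y - b0 - X[, -j, drop = FALSE] %*% b[-j]
      num <- sum(w * X[, j] * r_j)
      den <- sum(w * X[, j]^2) + 2 * lambda * gamma
      b[j] <- soft(num, lambda * (1 - gamma)) / den
    }
    b0 <- sum(w * (y - X %*% b)) / sum(w)
    if (max(abs(b - b_old)) < tol) break
  }
  list(coefficients = b, intercept = b0)
}

# Closed-form ridge-plus-Laplacian solution of
#   min ||z - Q theta||^2 + lambda2 theta' L theta
oracle_ridge_laplacian <- function(Q, z, L, lambda2) {
  solve(crossprod(Q) + lambda2 * L, drop(crossprod(Q, z)))
}

# Subgradient optimality check for
#   min ||z - Q theta||^2 + lambda1 ||theta||_1 + lambda2 theta' L theta
theta_kkt_violation <- function(theta, Q, z, L, lambda1, lambda2) {
  g <- 2 * (crossprod(Q) %*% theta - crossprod(Q, z)) +
    2 * lambda2 * (L %*% theta)
  g <- drop(g)
  viol <- numeric(length(theta))
  nz <- theta != 0
  viol[nz] <- abs(g[nz] + lambda1 * sign(theta[nz]))
  viol[!nz] <- pmax(abs(g[!nz]) - lambda1, 0)
  max(viol)
}

laplacian_of <- function(W) {
  W0 <- W; diag(W0) <- 0
  diag(rowSums(W0)) - W0
}

# Random orthonormal p x K matrix (for optimality spot-checks).
random_orthonormal <- function(p, K) {
  qr.Q(qr(matrix(rnorm(p * K), p, K)))
}
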