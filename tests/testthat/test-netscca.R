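test_that("Jaccard similarity matches set arithmetic", {
  sets <- list(g1 = c("a", "b", "c"), g2 = c("b", "c", "d"),
               g3 = c("x", "y"), g4 = character(),
               g5 = c("a", "b", "c"))
  W <- jaccard_similarity(sets)$W
  expect_equal(W["g1", "g2"], 0.5)      # |{b,c}| / |{a,b,c,d}|
  expect_equal(W["g1", "g5"], 1)        # identical nonempty sets
  expect_equal(W["g1", "g3"], 0)        # disjoint
  expect_equal(W["g4", "g4"], 0)        # empty set: union empty -> 0
  expect_equal(W, t(W))
  expect_true(all(W >= 0 & W <= 1))
})

test_that("neighbour sets and W are invariant to sample order", {
  sim <- simulate_varying_network(n = 40, p = 4, q = 2, seed = 12)
  net <- suppressWarnings(
    fit_sample_specific_network(sim$panel, sim$modulators,
                                kernel_config("adaptive_knn"),
                                penalty_spec("lasso", lambda = 3)))
  W1 <- jaccard_similarity(neighbor_sets(net))$W
  perm <- sample(nrow(net$edges))
  net2 <- net
  net2$edges <- net$edges[perm, , drop = FALSE]
  W2 <- jaccard_similarity(neighbor_sets(net2))$W
  expect_equal(W1, W2)
})

test_that("the pairwise fusion penalty equals the Laplacian quadratic form", {
  set.seed(3)
  for (rep in 1:10) {
    p <- 8
    W <- matrix(runif(p * p), p, p)
    W <- (W + t(W)) / 2
    L <- laplacian_of(W)
    theta <- rnorm(p)
    direct <- 0
    for (j in 1:(p - 1)) for (s in (j + 1):p)
      direct <- direct + (theta[j] - theta[s])^2 * W[j, s]
    expect_equal(drop(t(theta) %*% L %*% theta), direct, tolerance = 1e-10)
  }
})

test_that("the Gram factor reconstructs G and is PSD", {
  set.seed(5)
  # orthonormal single matrix: G = I, Q = I
  R <- qr.Q(qr(matrix(rnorm(20 * 4), 20, 4)))
  gf <- gram_matrix(list(R))
  expect_equal(gf$G, diag(4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(gf$Q, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  # random stack
  mats <- lapply(1:3, function(i) matrix(rnorm(30 * 6), 30, 6))
  gf <- gram_matrix(mats)
  expect_lt(norm(crossprod(gf$Q) - gf$G, "F") / norm(gf$G, "F"), 1e-8)
  expect_gte(min(gf$eigenvalues), -1e-10)
  expect_error(gram_matrix(list(matrix(c(1, NA, 2, 3), 2))), "finite")
})

test_that("unpenalized common components solve the trace problem", {
  G <- diag(c(4, 2, 1))
  A <- common_components_unpenalized(G, 1)
  expect_equal(abs(drop(A)), c(1, 0, 0), tolerance = 1e-12)
  # optimality spot-check against random orthonormal candidates
  set.seed(9)
  mats <- lapply(1:2, function(i) matrix(rnorm(25 * 6), 25, 6))
  gf <- gram_matrix(mats)
  A <- common_components_unpenalized(gf$G, 2)
  expect_equal(crossprod(A), diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  obj <- sum(diag(t(A) %*% gf$G %*% A))
  for (i in 1:100) {
    B <- random_orthonormal(6, 2)
    expect_lte(sum(diag(t(B) %*% gf$G %*% B)), obj + 1e-8)
  }
  expect_equal(sum(diag(t(common_components_unpenalized(gf$G, 6)) %*%
                          gf$G %*%
                          common_components_unpenalized(gf$G, 6))),
               sum(diag(gf$G)), tolerance = 1e-8)
  expect_error(common_components_unpenalized(gf$G, 7), "K")
})

test_that("theta step solves the fused lasso problem", {
  set.seed(13)
  p <- 5
  Q <- gram_matrix(list(matrix(rnorm(30 * p), 30, p)))$Q
  a <- random_orthonormal(p, 1)
  z <- drop(Q %*% a)
  W <- matrix(runif(p * p, 0, 0.5), p, p); W <- (W + t(W)) / 2; diag(W) <- 1
  L <- laplacian_of(W)
  # unpenalized limit: ordinary least squares
  th0 <- theta_step(Q, z, W, 0, 0)
  expect_equal(th0, drop(solve(crossprod(Q), crossprod(Q, z))),
               tolerance = 1e-7)
  # lambda2 = 0: matches the independent lasso oracle (no intercept; the
  # oracle's objective is 2x ours so its lambda is halved)
  th1 <- theta_step(Q, z, W, lambda1 = 0.3, lambda2 = 0)
  expect_lte(theta_kkt_violation(th1, Q, z, L, 0.3, 0), 1e-6)
  # lambda1 = 0: closed-form ridge-Laplacian solution
  th2 <- theta_step(Q, z, W, lambda1 = 0, lambda2 = 0.7)
  expect_equal(th2, drop(oracle_ridge_laplacian(Q, z, L, 0.7)),
               tolerance = 1e-8)
  # full problem satisfies the subgradient conditions
  th3 <- theta_step(Q, z, W, lambda1 = 0.2, lambda2 = 0.5)
  expect_lte(theta_kkt_violation(th3, Q, z, L, 0.2, 0.5), 1e-6)
  # a large fusion weight pulls connected coefficients together
  W2 <- diag(4) * 0
  W2[1, 2] <- W2[2, 1] <- 1
  Q4 <- gram_matrix(list(matrix(rnorm(40 * 4), 40, 4)))$Q
  z4 <- drop(Q4 %*% c(2, -1, 0.5, 0))
  gap0 <- abs(diff(theta_step(Q4, z4, W2, 0, 0)[1:2]))
  gap_big <- abs(diff(theta_step(Q4, z4, W2, 0, 500)[1:2]))
  expect_lt(gap_big, gap0 / 10)
})

test_that("the A step is the Procrustes maximizer", {
  set.seed(17)
  p <- 6; K <- 2
  Q <- gram_matrix(list(matrix(rnorm(30 * p), 30, p)))$Q
  # identity Gram: A equals an already-orthonormal Theta
  Th <- random_orthonormal(p, K)
  expect_equal(a_step(diag(p), Th), Th, tolerance = 1e-10)
  # orthonormality and optimality of tr(A' Q'Q Theta)
  Th <- matrix(rnorm(p * K), p, K)
  A <- a_step(Q, Th)
  expect_equal(crossprod(A), diag(K), tolerance = 1e-8, ignore_attr = TRUE)
  M <- crossprod(Q) %*% Th
  obj <- sum(diag(t(A) %*% M))
  for (i in 1:100)
    expect_lte(sum(diag(t(random_orthonormal(p, K)) %*% M)), obj + 1e-8)
  # sign equivariance
  Th2 <- Th; Th2[, 2] <- -Th2[, 2]
  A2 <- a_step(Q, Th2)
  expect_equal(A2[, 2], -A[, 2], tolerance = 1e-8)
  expect_equal(A2[, 1], A[, 1], tolerance = 1e-8)
})

test_that("with one matrix and no penalty the fit reduces to standard PCA", {
  set.seed(23)
  R1 <- matrix(rnorm(60 * 8), 60, 8) %*% diag(seq(2, 0.5, length.out = 8))
  fit <- netscca_fit(list(R1), K = 3, lambda1 = 0, lambda2 = 0)
  pc <- prcomp(R1, center = FALSE)$rotation[, 1:3]
  for (k in 1:3)
    expect_gte(loading_cosine(fit$loadings[, k], pc[, k]), 1 - 1e-6)
  # PCA objective is non-increasing across alternations
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
})

test_that("a dominating sparsity penalty empties the loadings", {
  set.seed(29)
  sim <- simulate_common_structure(q = 3, n = 60, p = 12, K = 1,
                                   support_size = 4, noise_sd = 0.2,
                                   seed = 29)
  fit <- netscca_fit(sim$effects, K = 1, lambda1 = 1e9, lambda2 = 0)
  expect_true(1L %in% fit$zero_components)
})

test_that("a shared sparse loading is recovered", {
  sim <- simulate_common_structure(q = 5, n = 200, p = 50, K = 1,
                                   support_size = 10, noise_sd = 0.1,
                                   seed = 31)
  W <- jaccard_similarity(sim$neighbor_sets)
  gf <- gram_matrix(sim$effects)
  # penalties on the scale of the problem: lambda1 relative to the
  # entry score |Q'Q a|, lambda2 relative to the Gram diagonal
  a1 <- common_components_unpenalized(gf$G, 1)
  lam1 <- 0.01 * max(abs(crossprod(gf$Q, gf$Q %*% a1)))
  lam2 <- 0.02 * mean(diag(gf$G))
  fit <- netscca_fit(gf, W, K = 1, lambda1 = lam1, lambda2 = lam2)
  est <- fit$loadings[, 1]
  expect_gte(loading_cosine(est, sim$loadings[, 1]), 0.9)
  m <- recovery_metrics(sim$loadings[, 1], est)
  expect_gte(m$f1, 0.8)
})
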