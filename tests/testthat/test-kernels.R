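test_that("constant-bandwidth Gaussian weights match the closed form", {
  m <- c(0, 1, 3, -2)
  w <- gaussian_weights(m, 1, 1)
  expect_equal(w$weights, exp(-m^2), tolerance = 1e-15)
  expect_identical(w$weights[1], 1)
  # bandwidth enters the denominator directly
  w2 <- gaussian_weights(m, 1, 4)
  expect_equal(w2$weights[2], exp(-1 / 4), tolerance = 1e-15)
  # huge bandwidth recovers uniform weights (pooled regression limit)
  w3 <- gaussian_weights(m, 1, 1e12)
  expect_true(all(abs(w3$weights - 1) < 1e-10))
  expect_error(gaussian_weights(m, 1, 0), "positive")
  expect_error(gaussian_weights(m, 1, -1), "positive")
})

test_that("weights are symmetric in modulator distance and maximal at the target", {
  set.seed(11)
  for (rep in 1:10) {
    m <- rnorm(20)
    a <- sample(20, 1)
    w <- gaussian_weights(m, a, runif(1, 0.1, 5))$weights
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(which.max(w), a)
    d <- abs(m - m[a])
    o <- order(d)
    expect_true(all(diff(w[o]) <= 1e-12))  # monotone in distance
  }
})

test_that("KNN bandwidth is the squared distance to the kth nearest other sample", {
  m <- c(0, 1, 3)
  expect_equal(knn_bandwidth(m, 1, 1), 1)
  expect_equal(knn_bandwidth(m, 1, 2), 9)
  expect_equal(knn_bandwidth(m, 3, 1), 4)
  # degenerate ties floor
  expect_equal(knn_bandwidth(rep(2, 5), 1, 3), 1e-8)
  expect_equal(knn_bandwidth(rep(2, 5), 1, 3, epsilon_floor = 1e-4), 1e-4)
  expect_error(knn_bandwidth(m, 1, 3), "k")
  expect_error(knn_bandwidth(m, 1, 0), "k")
})

test_that("adaptive weights evaluate the KNN-bandwidth kernel", {
  # b_knn = 1 (neighbour at distance 1), r(M) = 2 -> weight e^(-1/2)
  m <- c(0, 1, 2)
  w <- adaptive_weights(m, 1, k = 1, range_factor = 2)
  expect_equal(w$weights[1], 1)
  expect_equal(w$weights[2], exp(-1 / 2), tolerance = 1e-15)
  # identity with gaussian_weights when b = b_knn * r(M)
  set.seed(4)
  for (rep in 1:10) {
    m <- rnorm(15)
    a <- sample(15, 1)
    k <- sample(1:5, 1)
    rf <- runif(1, 0.5, 3)
    b <- knn_bandwidth(m, a, k) * rf
    expect_equal(adaptive_weights(m, a, k, rf)$weights,
                 gaussian_weights(m, a, b)$weights, tolerance = 1e-14)
  }
})

test_that("adaptive kernel widens in sparse regions", {
  # dense cluster near 0 plus one remote point: same k, 4x kth distance
  m <- c(0, 0.1, 0.2, 0.3, 4)
  rf <- modulator_range(m)
  wd <- adaptive_weights(m, 1, k = 2, range_factor = rf)$weights
  ws <- adaptive_weights(m, 5, k = 2, range_factor = rf)$weights
  # at any fixed distance the sparse target's kernel is wider
  for (d in c(0.5, 1, 2)) {
    bd <- knn_bandwidth(m, 1, 2) * rf
    bs <- knn_bandwidth(m, 5, 2) * rf
    expect_gte(exp(-d^2 / bs), exp(-d^2 / bd))
  }
  # every target keeps at least k samples above weight 0.01
  for (a in seq_along(m))
    expect_gte(sum(adaptive_weights(m, a, 2, rf)$weights > 0.01), 2)
})

test_that("constant bandwidth starves sparse-region targets of neighbours", {
  set.seed(21)
  m <- c(rnorm(80, 0, 0.25), rnorm(5, 6, 0.25))  # dense and sparse regions
  b <- 0.5
  n_dense <- sum(gaussian_weights(m, 1, b)$weights > 0.01)
  n_sparse <- sum(gaussian_weights(m, 81, b)$weights > 0.01)
  expect_lt(n_sparse, n_dense)
  # adaptive bandwidth with the same k repairs the sparse target
  rf <- modulator_range(m)
  for (a in c(1, 81, 85))
    expect_gte(sum(adaptive_weights(m, a, 10, rf)$weights > 0.01), 10)
})

test_that("modulator range is max minus min and rejects constants", {
  expect_equal(modulator_range(0:10), 10)
  expect_equal(modulator_range(c(-2, 3)), 5)
  expect_error(modulator_range(c(5, 5, 5)), "degenerate")
  M <- cbind(a = 0:4, b = c(1, 1, 1, 1, 3))
  expect_equal(unname(modulator_range(M)), c(4, 2))
})

test_that("multivariate Gaussian weights keep the determinant factor", {
  M <- rbind(c(0, 0), c(2, 0), c(1, 1))
  w <- multivariate_weights(M, 1, diag(2))
  expect_equal(w$weights[1], 1)
  expect_equal(w$weights[2], exp(-2), tolerance = 1e-15)
  # H = 4I, distance (2, 0): 0.25 * exp(-1/2)
  w4 <- multivariate_weights(M, 1, 4 * diag(2))
  expect_equal(w4$weights[2], 0.25 * exp(-0.5), tolerance = 1e-15)
  # h = 1 reduces to the univariate normal kernel
  m <- c(0, 1.3, -0.7)
  b <- 0.6
  w1 <- multivariate_weights(matrix(m), 1, matrix(b))
  expect_equal(w1$weights, b^(-0.5) * exp(-(m - m[1])^2 / (2 * b)),
               tolerance = 1e-14)
  expect_error(multivariate_weights(M, 1, matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(multivariate_weights(M, 1, matrix(c(1, 5, 2, 1), 2)),
               "symmetric")
})

test_that("default bandwidth matrix follows the diagonal Scott's rule", {
  set.seed(7)
  M <- matrix(rnorm(1000), ncol = 1)
  H <- default_bandwidth_matrix(M)
  expect_equal(H[1, 1], (1000^(-1 / 5))^2 * var(M[, 1]), tolerance = 0.2)
  M2 <- matrix(rnorm(300), 100, 3)
  H2 <- default_bandwidth_matrix(M2)
  expect_true(all(eigen(H2, symmetric = TRUE)$values > 0))
  expect_true(all(H2[upper.tri(H2)] == 0))
  expect_error(default_bandwidth_matrix(cbind(rnorm(50), rep(1, 50))),
               "degenerate")
})

test_that("compute_weights dispatches modes and resolves auto parameters", {
  set.seed(3)
  mt <- modulator_table(matrix(rnorm(30), ncol = 1))
  cc <- compute_weights(mt, 4, kernel_config("constant", bandwidth = 2))
  expect_equal(cc$weights,
               gaussian_weights(mt$values[, 1], 4, 2)$weights)
  ak <- compute_weights(mt, 4, kernel_config("adaptive_knn"))
  k <- ceiling(sqrt(30))
  expect_equal(ak$weights,
               adaptive_weights(mt$values[, 1], 4, k,
                                modulator_range(mt$values[, 1]))$weights)
  mt2 <- modulator_table(matrix(rnorm(60), ncol = 2))
  mv <- compute_weights(mt2, 2, kernel_config("multivariate"))
  expect_equal(mv$weights,
               multivariate_weights(mt2$values, 2,
                                    default_bandwidth_matrix(mt2$values))$weights)
})
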