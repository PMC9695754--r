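#' Modulator tables
#'
#' A modulator table holds one or more per-sample cancer characteristics
#' (e.g. drug sensitivity, survival risk) that index the varying
#' coefficients of a sample-specific network.  Internally it is a numeric
#' matrix of `n` samples by `h` characteristics with unique sample ids.
#'
#' @param values numeric matrix or vector; one row per sample.
#' @param sample_ids character vector of unique sample identifiers.
#' @param characteristic_names names for the columns of `values`.
#' @return An object of class `modulator_table`.
#' @export
modulator_table <- function(values, sample_ids = NULL,
                            characteristic_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (n < 2L) stop("a modulator table needs at least 2 samples")
  if (anyNA(values)) stop("modulator values must not contain missing values")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(sample_ids) != n) stop("sample_ids length must equal nrow(values)")
  if (is.null(characteristic_names)) {
    characteristic_names <- colnames(values)
    if (is.null(characteristic_names))
      characteristic_names <- paste0("characteristic", seq_len(ncol(values)))
  }
  dimnames(values) <- list(sample_ids, characteristic_names)
  structure(list(values = values, sample_ids = sample_ids,
                 characteristic_names = characteristic_names),
            class = "modulator_table")
}

#' @export
print.modulator_table <- function(x, ...) {
  cat(sprintf("modulator_table: %d samples x %d characteristic(s) [%s]\n",
              nrow(x$values), ncol(x$values),
              paste(x$characteristic_names, collapse = ", ")))
  invisible(x)
}

#' Kernel configuration
#'
#' Bundles the choice of sample-weighting kernel and its parameters.
#' Three modes are supported: `"constant"` (Gaussian kernel with a fixed
#' bandwidth), `"adaptive_knn"` (bandwidth set per target sample from the
#' squared distance to its k-th nearest neighbour, scaled by the modulator
#' range) and `"multivariate"` (Gaussian kernel with an h x h bandwidth
#' matrix for multi-characteristic modulators).
#'
#' @param mode one of `"constant"`, `"adaptive_knn"`, `"multivariate"`.
#' @param bandwidth positive bandwidth for `"constant"` mode.
#' @param k neighbour count for `"adaptive_knn"` mode; default
#'   `ceiling(sqrt(n))` is filled in at fit time when `NULL`.
#' @param range_factor positive scale r(M) for `"adaptive_knn"`, or
#'   `"auto"` to use the modulator range `max(m) - min(m)`.
#' @param bandwidth_matrix symmetric positive-definite h x h matrix for
#'   `"multivariate"` mode, or `"auto"` for the diagonal Scott's-rule
#'   default (see [default_bandwidth_matrix()]).
#' @param epsilon_floor lower floor for a degenerate adaptive bandwidth
#'   (all k nearest neighbours tied at the target's modulator value).
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(mode = c("constant", "adaptive_knn", "multivariate"),
                          bandwidth = NULL, k = NULL, range_factor = "auto",
                          bandwidth_matrix = "auto", epsilon_floor = 1e-8) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    if (is.null(bandwidth) || !is.numeric(bandwidth) || bandwidth <= 0)
      stop("constant mode requires a positive 'bandwidth'")
  }
  if (mode == "adaptive_knn" && !is.null(k)) {
    if (k < 1 || k != round(k)) stop("'k' must be a positive integer")
  }
  if (!identical(range_factor, "auto") &&
      (!is.numeric(range_factor) || range_factor <= 0))
    stop("'range_factor' must be positive or \"auto\"")
  if (epsilon_floor <= 0) stop("'epsilon_floor' must be positive")
  structure(list(mode = mode, bandwidth = bandwidth, k = k,
                 range_factor = range_factor,
                 bandwidth_matrix = bandwidth_matrix,
                 epsilon_floor = epsilon_floor),
            class = "kernel_config")
}

new_sample_weights <- function(weights, target_index) {
  structure(list(weights = as.numeric(weights),
                 target_index = as.integer(target_index),
                 effective_size = sum(weights)),
            class = "sample_weights")
}

#' @export
print.sample_weights <- function(x, ...) {
  cat(sprintf("sample_weights: n = %d, target = %d, effective size = %.3f\n",
              length(x$weights), x$target_index, x$effective_size))
  invisible(x)
}

#' Constant-bandwidth Gaussian sample weights
#'
#' Weight of sample i for modelling target sample `alpha`:
#' `exp(-(m_i - m_alpha)^2 / bandwidth)`.  Note the bandwidth enters the
#' denominator directly (not `2 b^2` as in textbook kernel conventions);
#' a textbook bandwidth `s` corresponds to `bandwidth = 2 s^2` here.
#'
#' @param m numeric modulator vector, length n.
#' @param alpha index of the target sample in `m`.
#' @param bandwidth positive kernel bandwidth.
#' @return A `sample_weights` object; the weight at `alpha` is 1.
#' @export
gaussian_weights <- function(m, alpha, bandwidth) {
  m <- as.numeric(m)
  stopifnot(alpha >= 1, alpha <= length(m))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("'bandwidth' must be a positive scalar")
  w <- exp(-((m - m[alpha])^2) / bandwidth)
  new_sample_weights(w, alpha)
}

#' Adaptive KNN bandwidth for one target sample
#'
#' Squared distance between the target's modulator value and that of its
#' k-th nearest *other* sample, `(m_alpha - m_alpha^(kth))^2`.  Ties in
#' distance are broken by sample order, so the result is deterministic.
#' When the k nearest neighbours all share the target's value the squared
#' distance is zero and `epsilon_floor` is returned instead.
#'
#' @inheritParams gaussian_weights
#' @param k neighbour rank, `1 <= k <= n - 1`.
#' @param epsilon_floor floor for the degenerate all-ties case.
#' @return A nonnegative scalar bandwidth.
#' @export
knn_bandwidth <- function(m, alpha, k, epsilon_floor = 1e-8) {
  m <- as.numeric(m)
  n <- length(m)
  stopifnot(alpha >= 1, alpha <= n)
  if (k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (k >= n) stop(sprintf("'k' must be < n (= %d); got k = %d", n, k))
  d <- abs(m[-alpha] - m[alpha])
  kth <- sort(d, method = "radix")[k]
  b <- kth^2
  if (b < epsilon_floor) b <- epsilon_floor
  b
}

#' Adaptive-bandwidth Gaussian sample weights
#'
#' As [gaussian_weights()] but with a per-target bandwidth
#' `knn_bandwidth(m, alpha, k) * range_factor`: targets in sparse regions
#' of the modulator distribution (whose k-th neighbour is far) receive a
#' wider kernel, so at least k samples always carry substantial weight.
#'
#' @inheritParams knn_bandwidth
#' @param range_factor positive dispersion scale r(M); use
#'   [modulator_range()] for the default `max(m) - min(m)`.
#' @return A `sample_weights` object.
#' @export
adaptive_weights <- function(m, alpha, k, range_factor,
                             epsilon_floor = 1e-8) {
  if (!is.numeric(range_factor) || range_factor <= 0)
    stop("'range_factor' must be positive")
  b <- knn_bandwidth(m, alpha, k, epsilon_floor)
  gaussian_weights(m, alpha, b * range_factor)
}

#' Range of a modulator
#'
#' Default dispersion scale r(M): `max - min` of each characteristic.
#'
#' @param m numeric vector or matrix (columns = characteristics).
#' @return Scalar for a vector input, named vector for a matrix.
#' @export
modulator_range <- function(m) {
  f <- function(v) {
    r <- max(v) - min(v)
    if (r <= 0) stop("modulator is constant: range is degenerate")
    r
  }
  if (is.matrix(m)) apply(m, 2L, f) else f(as.numeric(m))
}

#' Multivariate Gaussian sample weights
#'
#' For h-dimensional modulators, the similarity of sample i to target
#' `alpha` is `|H|^(-1/2) exp(-1/2 d' H^{-1} d)` with
#' `d = m_i - m_alpha`.  The normalizing determinant factor is kept, so
#' weights can exceed 1 when `|H| < 1`.
#'
#' @param M numeric matrix n x h of modulator values.
#' @param alpha target sample row index.
#' @param H symmetric positive-definite h x h bandwidth matrix.
#' @return A `sample_weights` object.
#' @export
multivariate_weights <- function(M, alpha, H) {
  M <- as.matrix(M)
  H <- as.matrix(H)
  h <- ncol(M)
  stopifnot(alpha >= 1, alpha <= nrow(M))
  if (nrow(H) != h || ncol(H) != h) stop("'H' must be h x h")
  if (max(abs(H - t(H))) > 1e-10 * max(1, max(abs(H))))
    stop("'H' must be symmetric")
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'H' must be positive definite")
  R <- chol(H)
  D <- sweep(M, 2L, M[alpha, , drop = TRUE])
  # Mahalanobis distances via the Cholesky factor
  Z <- backsolve(R, t(D), transpose = TRUE)
  md2 <- colSums(Z^2)
  detH <- prod(diag(R))^2
  w <- detH^(-0.5) * exp(-0.5 * md2)
  new_sample_weights(w, alpha)
}

#' Default bandwidth matrix (diagonal Scott's rule)
#'
#' Diagonal matrix with per-characteristic entries
#' `(n^(-1/(h+4)) * sd_j)^2`, the squared Scott's-rule bandwidths.
#'
#' @param M numeric matrix n x h of modulator values.
#' @return A symmetric positive-definite diagonal h x h matrix.
#' @export
default_bandwidth_matrix <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M)
  h <- ncol(M)
  if (n <= h) stop("need more samples than characteristics")
  s <- apply(M, 2L, stats::sd)
  if (any(s <= 0)) stop("zero-variance characteristic: bandwidth degenerate")
  diag((n^(-1 / (h + 4)) * s)^2, nrow = h)
}

#' Compute sample weights under a kernel configuration
#'
#' Dispatches to the constant, adaptive-KNN or multivariate kernel and
#' resolves `"auto"` parameters from the modulator table.
#'
#' @param modulators a [modulator_table()].
#' @param alpha target sample index.
#' @param config a [kernel_config()].
#' @return A `sample_weights` object.
#' @export
compute_weights <- function(modulators, alpha, config) {
  stopifnot(inherits(modulators, "modulator_table"),
            inherits(config, "kernel_config"))
  V <- modulators$values
  n <- nrow(V)
  switch(config$mode,
    constant = gaussian_weights(V[, 1L], alpha, config$bandwidth),
    adaptive_knn = {
      k <- if (is.null(config$k)) ceiling(sqrt(n)) else config$k
      rf <- if (identical(config$range_factor, "auto"))
        modulator_range(V[, 1L]) else config$range_factor
      adaptive_weights(V[, 1L], alpha, k, rf, config$epsilon_floor)
    },
    multivariate = {
      H <- if (identical(config$bandwidth_matrix, "auto"))
        default_bandwidth_matrix(V) else config$bandwidth_matrix
      multivariate_weights(V, alpha, H)
    })
}
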