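#' Simulate a non-uniform modulator
#'
#' Draws per-sample characteristic values (e.g. drug sensitivities) from
#' a Gaussian mixture.  The default two-component mixture places most
#' samples in a dense region and a minority in a wide sparse tail,
#' emulating the skewed, non-uniform distributions of real drug
#' sensitivities.
#'
#' The default parameters emulate a drug sensitivity normalized to a
#' unit scale before network analysis, as is conventional for
#' modulator-indexed models: a dense mode around 0.3 holding 80% of the
#' cohort and a wider sparse mode around 0.75.
#'
#' @param n number of samples.
#' @param means,sds,weights mixture component parameters; `weights` must
#'   sum to 1.
#' @param seed RNG seed.
#' @return Numeric vector of length n with an integer `"component"`
#'   attribute recording each draw's mixture component.
#' @export
simulate_modulator <- function(n, means = c(0.3, 0.8),
                               sds = c(0.1, 0.1),
                               weights = c(0.75, 0.25), seed = 1L) {
  if (length(means) != length(sds) || length(means) != length(weights))
    stop("mixture parameter lengths disagree")
  if (any(sds < 0) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("invalid mixture: sds nonnegative, weights summing to 1")
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  m <- stats::rnorm(n, means[comp], sds[comp])
  attr(m, "component") <- comp
  m
}

#' Default varying-coefficient ground truth
#'
#' For every target, regulator 1 has a linear-in-modulator coefficient,
#' regulator 2 a threshold coefficient that vanishes above a modulator
#' cutoff, regulator 3 a constant coefficient, and all others are zero.
#'
#' @param slope slope of the linear edge (`beta_1 = slope * m`).
#' @param threshold_value,threshold_cutoff the threshold edge equals
#'   `threshold_value` for `m <= threshold_cutoff` and 0 above it.
#' @param constant_value coefficient of the constant edge.
#' @return A function `(j, l, m) -> coefficient`, vectorized over `m`.
#' @export
default_truth_fn <- function(slope = 4, threshold_value = 2,
                             threshold_cutoff = 0.5, constant_value = 1.5) {
  function(j, l, m) {
    if (j == 1L) slope * m
    else if (j == 2L) ifelse(m <= threshold_cutoff, threshold_value, 0)
    else if (j == 3L) rep(constant_value, length(m))
    else rep(0, length(m))
  }
}

#' Simulate expression from a varying-coefficient network
#'
#' Generates regulator expression as iid standard normal (optionally
#' with exchangeable correlation), draws a non-uniform modulator, and
#' builds each target as
#' `y_al = sum_j beta_jl(m_a) x_aj + eps`, `eps ~ N(0, sigma^2)`.
#' With `noise_sd = "auto"`, sigma is set so the signal-to-noise ratio
#' (mean conditional signal variance over sigma^2) is `snr`.
#'
#' @param n,p,q samples, regulators, targets.
#' @param truth_fn coefficient function `(j, l, m)`; default
#'   [default_truth_fn()].
#' @param noise_sd noise standard deviation, or `"auto"`.
#' @param snr target signal-to-noise ratio for `"auto"`.
#' @param rho exchangeable correlation between regulators (0 = iid).
#' @param modulator optional pre-drawn modulator vector; default drawn by
#'   [simulate_modulator()] with the same seed.
#' @param seed RNG seed.
#' @return A list with `panel` ([expression_panel()]), `modulators`
#'   ([modulator_table()]), and `truth` (list with `beta` the true
#'   n x p x q coefficient array, `truth_fn`, `noise_sd`, `seed`).
#' @export
simulate_varying_network <- function(n = 300L, p = 10L, q = 5L,
                                     truth_fn = default_truth_fn(),
                                     noise_sd = "auto", snr = 3,
                                     rho = 0, modulator = NULL,
                                     seed = 1L) {
  if (is.null(modulator)) modulator <- simulate_modulator(n, seed = seed)
  m <- as.numeric(modulator)
  set.seed(seed + 1L)
  X <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    z <- stats::rnorm(n)
    X <- sqrt(1 - rho) * X + sqrt(rho) * z
  }
  beta <- array(0, c(n, p, q))
  for (l in seq_len(q)) for (j in seq_len(p))
    beta[, j, l] <- truth_fn(j, l, m)
  signal <- vapply(seq_len(q), function(l)
    rowSums(beta[, , l] * X), numeric(n))
  if (identical(noise_sd, "auto")) {
    # mean conditional signal variance: E_a sum_j beta_jl(m_a)^2
    msv <- mean(vapply(seq_len(q), function(l)
      mean(rowSums(beta[, , l]^2)), numeric(1)))
    noise_sd <- sqrt(msv / snr)
  }
  Y <- signal + matrix(stats::rnorm(n * q, 0, noise_sd), n, q)
  sample_ids <- sprintf("S%03d", seq_len(n))
  regulator_ids <- sprintf("R%02d", seq_len(p))
  target_ids <- sprintf("T%02d", seq_len(q))
  dimnames(X) <- list(sample_ids, regulator_ids)
  dimnames(Y) <- list(sample_ids, target_ids)
  dimnames(beta) <- list(sample_ids, regulator_ids, target_ids)
  list(panel = expression_panel(X, Y),
       modulators = modulator_table(matrix(m, ncol = 1,
                                           dimnames = list(sample_ids,
                                                           "modulator"))),
       truth = list(beta = beta, truth_fn = truth_fn,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate effect matrices sharing a sparse common structure
#'
#' Builds q regulatory-effect matrices `R_l = S_l V' + E` with a shared
#' sparse orthonormal loading matrix `V` (p x K, disjoint supports of
#' `support_size` genes per component), scores `S_l ~ N(0, score_sd^2)`
#' and entrywise Gaussian noise.  Neighbour sets linking genes that
#' share a component's support are returned for building the similarity
#' graph.
#'
#' @param q,n,p matrices, samples, genes.
#' @param K components.
#' @param support_size nonzero genes per component (`K * support_size <=
#'   p`).
#' @param noise_sd entrywise noise standard deviation.
#' @param score_sd score standard deviation.
#' @param seed RNG seed.
#' @return A list with `effects` (`regulatory_effects`), `loadings`
#'   (true p x K matrix), `neighbor_sets`.
#' @export
simulate_common_structure <- function(q = 5L, n = 200L, p = 50L, K = 1L,
                                      support_size = 10L, noise_sd = 0.1,
                                      score_sd = 1, seed = 1L) {
  if (K * support_size > p) stop("'support_size' too large for p and K")
  set.seed(seed)
  V <- matrix(0, p, K)
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * support_size + 1L):(k * support_size)
    # signed magnitudes bounded away from zero, so every support entry
    # is in principle recoverable
    v <- sample(c(-1, 1), support_size, replace = TRUE) *
      stats::runif(support_size, 0.5, 1.5)
    V[idx, k] <- v / sqrt(sum(v^2))
  }
  mats <- lapply(seq_len(q), function(l) {
    S <- matrix(stats::rnorm(n * K, 0, score_sd), n, K)
    S %*% t(V) + matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  })
  gene_ids <- sprintf("G%03d", seq_len(p))
  rownames(V) <- gene_ids
  nb <- stats::setNames(vector("list", p), gene_ids)
  for (j in seq_len(p)) nb[[j]] <- character()
  for (k in seq_len(K)) {
    sup <- which(V[, k] != 0)
    for (j in sup) nb[[j]] <- union(nb[[j]], gene_ids[setdiff(sup, j)])
  }
  eff <- regulatory_effect_set(mats, regulator_ids = gene_ids)
  list(effects = eff, loadings = V, neighbor_sets = nb)
}

#' Simulate a drug response driven by designated causal edges
#'
#' The sensitivity of each sample is a linear combination of the effect
#' values of the causal edges plus Gaussian noise, so that percentile
#' labeling yields classes separable through exactly those edges.
#'
#' @param effects a `regulatory_effects` object.
#' @param causal_edges data.frame with columns `target`, `regulator`.
#' @param coefficients numeric weights, one per causal edge.
#' @param noise_sd noise standard deviation.
#' @param seed RNG seed.
#' @return Named numeric sensitivity vector over all samples.
#' @export
simulate_drug_response <- function(effects, causal_edges, coefficients,
                                   noise_sd = 1, seed = 1L) {
  stopifnot(inherits(effects, "regulatory_effects"),
            nrow(causal_edges) == length(coefficients))
  n <- length(effects$sample_ids)
  signal <- numeric(n)
  for (i in seq_len(nrow(causal_edges))) {
    l <- match(causal_edges$target[i], effects$target_ids)
    j <- match(causal_edges$regulator[i], effects$regulator_ids)
    if (is.na(l) || is.na(j)) stop("causal edge not present in effects")
    signal <- signal + coefficients[i] * effects$matrices[[l]][, j]
  }
  set.seed(seed)
  stats::setNames(signal + stats::rnorm(n, 0, noise_sd),
                  effects$sample_ids)
}

#' Support and loading recovery metrics
#'
#' Compares an estimated coefficient structure with the truth: support
#' precision/recall/F1 (an entry is "in the support" when nonzero),
#' coefficient RMSE, and for loading vectors the absolute cosine
#' similarity (sign-invariant).
#'
#' @param truth,estimate numeric arrays of identical shape.
#' @return A list with `precision`, `recall`, `f1`, `rmse`.
#' @export
recovery_metrics <- function(truth, estimate) {
  if (!identical(dim(truth), dim(estimate)) ||
      length(truth) != length(estimate))
    stop("shape mismatch between truth and estimate")
  ts <- truth != 0
  es <- estimate != 0
  tp <- sum(ts & es)
  precision <- if (sum(es)) tp / sum(es) else NA_real_
  recall <- if (sum(ts)) tp / sum(ts) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       rmse = sqrt(mean((truth - estimate)^2)))
}

#' @rdname recovery_metrics
#' @param a,b numeric vectors of equal length.
#' @return `loading_cosine`: absolute cosine similarity in `[0, 1]`.
#' @export
loading_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  abs(sum(a * b)) / (na * nb)
}
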