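#' Expression panel
#'
#' Holds regulator expression `X` (n x p) and target expression `Y`
#' (n x q) with aligned sample ids.  Regulator and target sets may
#' overlap (or coincide); self-loops are excluded at fit time.
#'
#' @param X numeric matrix n x p of regulator expression.
#' @param Y numeric matrix n x q of target expression.
#' @param regulator_ids,target_ids,sample_ids identifiers; defaults taken
#'   from dimnames.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(X, Y, regulator_ids = NULL, target_ids = NULL,
                             sample_ids = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("'X' and 'Y' must have the same sample rows")
  if (anyNA(X) || anyNA(Y)) stop("expression matrices must be complete")
  n <- nrow(X)
  ids <- function(given, dn, prefix, m) {
    out <- if (!is.null(given)) given else if (!is.null(dn)) dn
           else paste0(prefix, seq_len(m))
    if (anyDuplicated(out)) stop(sprintf("duplicate %s ids", prefix))
    if (length(out) != m) stop(sprintf("%s ids have wrong length", prefix))
    out
  }
  regulator_ids <- ids(regulator_ids, colnames(X), "regulator", ncol(X))
  target_ids <- ids(target_ids, colnames(Y), "target", ncol(Y))
  sample_ids <- ids(sample_ids, rownames(X), "sample", n)
  dimnames(X) <- list(sample_ids, regulator_ids)
  dimnames(Y) <- list(sample_ids, target_ids)
  structure(list(X = X, Y = Y, regulator_ids = regulator_ids,
                 target_ids = target_ids, sample_ids = sample_ids),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel: %d samples, %d regulators, %d targets\n",
              length(x$sample_ids), length(x$regulator_ids),
              length(x$target_ids)))
  invisible(x)
}

#' Keep the most variable genes
#'
#' Returns the indices of the genes whose sample variance lies in the top
#' `top_fraction` of all genes: `ceiling(top_fraction * G)` genes, ties
#' broken by gene order.
#'
#' @param expression numeric matrix, samples x genes.
#' @param top_fraction fraction in `(0, 1]` of genes to keep.
#' @return Integer vector of selected gene column indices (increasing).
#' @export
variance_filter <- function(expression, top_fraction) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("'top_fraction' must be in (0, 1]")
  expression <- as.matrix(expression)
  G <- ncol(expression)
  v <- apply(expression, 2L, stats::var)
  keep <- ceiling(top_fraction * G)
  ord <- order(-v, seq_len(G))  # decreasing variance, ties by gene order
  sort(ord[seq_len(keep)])
}

#' Fit a sample-characteristic-specific network
#'
#' For every target gene and every target sample, computes kernel weights
#' over all samples from the modulator, rescales them to sum to n (so one
#' lambda grid is comparable across dense and sparse modulator regions),
#' and fits a weighted penalized regression of the target on all
#' regulators.  A nonzero fitted coefficient `beta_hat_jl(m_alpha)` is a
#' directed edge regulator j -> target l in sample alpha's network.
#'
#' @param panel an [expression_panel()].
#' @param modulators a [modulator_table()] aligned with the panel.
#' @param kernel a [kernel_config()].
#' @param penalty a [penalty_spec()]; with `lambda = "auto"` one lambda
#'   is selected per target gene (minimizing the weighted BIC averaged
#'   over target samples) unless `lambda_per_sample = TRUE`.
#' @param lambda_per_sample select lambda separately for every
#'   (sample, target) fit.
#' @param ess_warn_threshold warn when the raw effective sample size
#'   (sum of kernel weights before rescaling) falls below this.
#' @param verbose print per-target progress.
#' @return An object of class `sample_network`: a list with `edges`
#'   (data.frame of nonzero coefficients: sample, regulator, target,
#'   beta), `intercepts` (n x q), `diagnostics` (per sample/target
#'   effective size and lambda), the ids, and the configs used.
#' @export
fit_sample_specific_network <- function(panel, modulators, kernel,
                                        penalty = penalty_spec("lasso"),
                                        lambda_per_sample = FALSE,
                                        ess_warn_threshold = 10,
                                        verbose = FALSE) {
  stopifnot(inherits(panel, "expression_panel"),
            inherits(modulators, "modulator_table"))
  n <- length(panel$sample_ids)
  if (nrow(modulators$values) != n ||
      !identical(modulators$sample_ids, panel$sample_ids))
    stop("modulator rows do not align with panel samples")
  p <- length(panel$regulator_ids)
  q <- length(panel$target_ids)

  # precompute weights per target sample (kernel does not depend on l)
  W <- vapply(seq_len(n), function(a) {
    w <- compute_weights(modulators, a, kernel)$weights
    w
  }, numeric(n))  # n x n, column a = weights for target sample a
  ess_raw <- colSums(W)
  low <- which(ess_raw < ess_warn_threshold)
  if (length(low))
    warning(sprintf("%d target sample(s) have effective size < %g",
                    length(low), ess_warn_threshold))
  Wn <- sweep(W, 2L, ess_raw / n, "/")  # rescaled to sum to n

  edges <- vector("list", q)
  intercepts <- matrix(NA_real_, n, q,
                       dimnames = list(panel$sample_ids, panel$target_ids))
  diag_list <- vector("list", q)
  n_failed <- 0L

  for (l in seq_len(q)) {
    tid <- panel$target_ids[l]
    keep_j <- which(panel$regulator_ids != tid)  # drop self-loop column
    Xl <- panel$X[, keep_j, drop = FALSE]
    yl <- panel$Y[, l]
    lam_l <- penalty$lambda
    beta_mat <- matrix(0, n, length(keep_j))
    lam_used <- numeric(n)
    ok <- rep(TRUE, n)

    if (identical(penalty$lambda, "auto") && !lambda_per_sample) {
      # one lambda per target: minimize weighted BIC averaged over alpha
      lam_l <- select_lambda_shared(Xl, yl, Wn, penalty)
    }
    pen_a <- penalty
    for (a in seq_len(n)) {
      w <- Wn[, a]
      pen_a$lambda <- if (identical(penalty$lambda, "auto") &&
                          lambda_per_sample) "auto" else lam_l
      fit <- tryCatch(
        fit_penalized_regression(Xl, yl, pen_a, weights = w),
        error = function(e) e)
      if (inherits(fit, "error")) {
        ok[a] <- FALSE
        n_failed <- n_failed + 1L
        next
      }
      beta_mat[a, ] <- fit$coefficients
      intercepts[a, l] <- fit$intercept
      lam_used[a] <- fit$lambda
    }
    nz <- which(beta_mat != 0, arr.ind = TRUE)
    edges[[l]] <- if (nrow(nz)) {
      data.frame(sample = panel$sample_ids[nz[, 1L]],
                 regulator = panel$regulator_ids[keep_j][nz[, 2L]],
                 target = tid,
                 beta = beta_mat[nz],
                 stringsAsFactors = FALSE)
    } else NULL
    diag_list[[l]] <- data.frame(
      sample = panel$sample_ids, target = tid,
      effective_size = ess_raw, lambda = lam_used, fitted = ok,
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("target %s: %d nonzero edges", tid,
                      if (is.null(edges[[l]])) 0L else nrow(edges[[l]])))
  }
  if (n_failed == n * q) stop("all per-(sample, target) fits failed")

  structure(list(
    edges = do.call(rbind, edges[!vapply(edges, is.null, logical(1))]),
    intercepts = intercepts,
    diagnostics = do.call(rbind, diag_list),
    sample_ids = panel$sample_ids,
    regulator_ids = panel$regulator_ids,
    target_ids = panel$target_ids,
    kernel = kernel, penalty = penalty),
    class = "sample_network")
}

# Shared-lambda selection for one target: weighted BIC on a common grid,
# averaged over target samples (warm-started paths per sample).
select_lambda_shared <- function(X, y, Wn, penalty) {
  n <- nrow(X)
  # grid anchored at the largest per-sample entry point
  stds <- vector("list", n)
  lmax <- 0
  for (a in seq_len(n)) {
    w <- Wn[, a]
    std <- weighted_standardize(X, y, w)
    cvec <- drop(crossprod(std$Xs, w * std$yc))
    stds[[a]] <- list(std = std, w = w,
                      S = crossprod(std$Xs, w * std$Xs), cvec = cvec)
    lmax <- max(lmax, max(abs(cvec)))
  }
  grid <- if (!is.null(penalty$lambda_grid)) penalty$lambda_grid else {
    l1_share <- max(1 - penalty$gamma, 0.05)
    exp(seq(log(lmax / l1_share),
            log(lmax / l1_share * penalty$lambda_min_ratio),
            length.out = penalty$n_lambda))
  }
  if (length(grid) == 1L) return(grid)
  crit <- numeric(length(grid))
  for (a in seq_len(n)) {
    st <- stds[[a]]
    path <- gram_path(st$S, st$cvec, grid, penalty$gamma)
    crit <- crit + path_refit_bic(path, st$S, st$cvec, st$std$Xs,
                                  st$std$yc, st$w)
  }
  grid[which.min(crit)]
}

#' @export
print.sample_network <- function(x, ...) {
  ne <- if (is.null(x$edges)) 0L else nrow(x$edges)
  cat(sprintf(
    "sample_network: %d samples, %d regulators, %d targets, %d nonzero edges\n",
    length(x$sample_ids), length(x$regulator_ids), length(x$target_ids), ne))
  invisible(x)
}

#' Coefficients of one sample's network as a matrix
#'
#' @param network a `sample_network`.
#' @param sample sample id or index.
#' @return A p x q matrix of coefficients (regulators x targets).
#' @export
network_coef_matrix <- function(network, sample) {
  stopifnot(inherits(network, "sample_network"))
  sid <- if (is.character(sample)) sample else network$sample_ids[sample]
  B <- matrix(0, length(network$regulator_ids), length(network$target_ids),
              dimnames = list(network$regulator_ids, network$target_ids))
  e <- network$edges
  if (!is.null(e)) {
    e <- e[e$sample == sid, , drop = FALSE]
    if (nrow(e)) B[cbind(e$regulator, e$target)] <- e$beta
  }
  B
}

#' Coefficient tensor as a dense array
#'
#' @param network a `sample_network`.
#' @return An n x p x q array of coefficients.
#' @export
network_coef_array <- function(network) {
  n <- length(network$sample_ids)
  p <- length(network$regulator_ids)
  q <- length(network$target_ids)
  A <- array(0, c(n, p, q),
             dimnames = list(network$sample_ids, network$regulator_ids,
                             network$target_ids))
  e <- network$edges
  if (!is.null(e)) {
    i <- match(e$sample, network$sample_ids)
    j <- match(e$regulator, network$regulator_ids)
    k <- match(e$target, network$target_ids)
    A[cbind(i, j, k)] <- e$beta
  }
  A
}
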