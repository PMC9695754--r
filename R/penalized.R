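#' Penalty specification
#'
#' Describes the penalized-regression family used for every per-sample
#' network fit.  The objective minimized is
#' `1/2 sum_i w_i (y_i - sum_j beta_j x_ij)^2 + P(beta)` with
#' \itemize{
#'   \item ridge: `P = lambda * sum beta^2`
#'   \item lasso: `P = lambda * sum |beta|`
#'   \item elastic_net: `P = lambda * sum (gamma * beta^2 + (1 - gamma) * |beta|)`
#' }
#' Note the elastic-net mixing puts `gamma` on the ridge part.
#'
#' @param family `"ridge"`, `"lasso"` or `"elastic_net"`.
#' @param lambda positive penalty weight, or `"auto"` to select from
#'   `lambda_grid` by `selection`.
#' @param gamma ridge mixing weight in `[0, 1]`; required for
#'   `elastic_net`.
#' @param lambda_grid decreasing positive grid used when `lambda =
#'   "auto"`; `NULL` means a data-driven log-spaced grid.
#' @param n_lambda,lambda_min_ratio shape of the data-driven grid.
#' @param selection `"weighted_bic"` (default) or `"weighted_cv"`.
#' @param cv_folds folds for `"weighted_cv"`.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(family = c("lasso", "ridge", "elastic_net"),
                         lambda = "auto", gamma = NULL, lambda_grid = NULL,
                         n_lambda = 20L, lambda_min_ratio = 1e-3,
                         selection = c("weighted_bic", "weighted_cv"),
                         cv_folds = 5L) {
  family <- match.arg(family)
  selection <- match.arg(selection)
  if (family == "elastic_net") {
    if (is.null(gamma) || gamma < 0 || gamma > 1)
      stop("elastic_net requires 'gamma' in [0, 1]")
  } else {
    gamma <- switch(family, ridge = 1, lasso = 0)
  }
  if (!identical(lambda, "auto") &&
      (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0))
    stop("'lambda' must be a nonnegative scalar or \"auto\"")
  if (!is.null(lambda_grid)) {
    if (!is.numeric(lambda_grid) || length(lambda_grid) == 0L ||
        any(lambda_grid < 0))
      stop("'lambda_grid' must be a nonempty nonnegative numeric vector")
    lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  }
  structure(list(family = family, lambda = lambda, gamma = gamma,
                 lambda_grid = lambda_grid, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio, selection = selection,
                 cv_folds = as.integer(cv_folds)),
            class = "penalty_spec")
}

# Weighted standardization of a design matrix and response.
# Normalized weights are used for the moments, so the standardization is
# invariant to rescaling of the weights.
weighted_standardize <- function(X, y, w) {
  wn <- w / sum(w)
  xm <- drop(crossprod(X, wn))
  Xc <- sweep(X, 2L, xm)
  xs <- sqrt(drop(crossprod(Xc^2, wn)))
  xs[xs < 1e-12] <- 1  # constant predictor: leave centered, coef will be 0
  Xs <- sweep(Xc, 2L, xs, "/")
  ym <- sum(wn * y)
  list(Xs = Xs, yc = y - ym, xm = xm, xs = xs, ym = ym)
}

# Solve the standardized Gram-form problem for one lambda.
# S, c are on the standardized scale; returns standardized coefficients.
solve_gram <- function(S, cvec, lambda, gamma, beta0 = NULL,
                       tol = 1e-7, max_iter = 1e5L) {
  p <- length(cvec)
  if (is.null(beta0)) beta0 <- numeric(p)
  Sq <- S
  if (gamma > 0 && lambda > 0) diag(Sq) <- diag(Sq) + 2 * lambda * gamma
  fit <- cd_gram(Sq, cvec, lambda * (1 - gamma), beta0, tol,
                 as.integer(max_iter))
  fit
}

# Data-driven lambda grid: from the smallest lambda that zeroes every
# coefficient down by lambda_min_ratio, log-spaced.
lambda_grid_for <- function(cvec, penalty) {
  if (!is.null(penalty$lambda_grid)) return(penalty$lambda_grid)
  l1_share <- max(1 - penalty$gamma, 0.05)
  lmax <- max(abs(cvec)) / l1_share
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * penalty$lambda_min_ratio),
          length.out = penalty$n_lambda))
}

#' Weighted penalized regression
#'
#' Minimizes `1/2 sum_i w_i (y_i - b0 - x_i' beta)^2 + P(beta)` by
#' coordinate descent on the Gram form.  Predictors are standardized to
#' weighted unit variance internally and the response weighted-centered;
#' returned coefficients are on the original scale, with an intercept.
#'
#' @param X numeric matrix n x p of predictors.
#' @param y numeric response vector, length n.
#' @param penalty a [penalty_spec()]; a scalar `lambda` there is used
#'   directly, `"auto"` triggers [select_lambda()].
#' @param weights nonnegative observation weights (default uniform).
#' @param standardize scale predictors to weighted unit variance before
#'   penalizing (default); with `FALSE` the penalty applies to the raw
#'   coefficients exactly as in the displayed objective.
#' @param tol,max_iter coordinate-descent convergence controls.
#' @return A list with `coefficients` (length p), `intercept`, `lambda`,
#'   `df` (nonzero count), `weighted_rss`, `converged`.
#' @export
fit_penalized_regression <- function(X, y, penalty = penalty_spec("lasso"),
                                     weights = NULL, standardize = TRUE,
                                     tol = 1e-7, max_iter = 1e5L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("dimensions of 'X' and 'y' disagree")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("'weights' must have length n")
  if (any(weights < 0)) stop("'weights' must be nonnegative")
  if (sum(weights > 0) < 2L)
    stop("degenerate weights: need at least 2 samples with positive weight")

  std <- weighted_standardize(X, y, weights)
  if (!standardize) {
    std$Xs <- sweep(std$Xs, 2L, std$xs, "*")  # undo scaling, keep centering
    std$xs <- rep(1, p)
  }
  wy <- weights * std$yc
  if (sum(wy^2) == 0) {
    warning("response is constant under the weights; intercept-only model")
    return(list(coefficients = stats::setNames(numeric(p), colnames(X)),
                intercept = std$ym, lambda = NA_real_, df = 0L,
                weighted_rss = 0, converged = TRUE))
  }
  S <- crossprod(std$Xs, weights * std$Xs)
  cvec <- drop(crossprod(std$Xs, wy))

  lambda <- penalty$lambda
  if (identical(lambda, "auto"))
    lambda <- select_lambda(X, y, weights, penalty)

  fit <- solve_gram(S, cvec, lambda, penalty$gamma, tol = tol,
                    max_iter = max_iter)
  bs <- fit$beta
  beta <- bs / std$xs
  intercept <- std$ym - sum(beta * std$xm)
  r <- y - intercept - drop(X %*% beta)
  list(coefficients = stats::setNames(beta, colnames(X)),
       intercept = intercept, lambda = lambda, df = sum(beta != 0),
       weighted_rss = sum(weights * r^2), converged = fit$converged)
}

# Weighted BIC with the Kish effective sample size n_k = (sum w)^2 /
# sum(w^2): under concentrated kernel weights the information content is
# n_k, not sum(w); with uniform weights n_k = n and this is the usual BIC.
weighted_bic <- function(wrss, w, df) {
  nk <- sum(w)^2 / sum(w^2)
  nk * log(max(wrss, 1e-300) / sum(w)) + df * log(nk)
}

# BIC along a lasso path, evaluated on the weighted OLS refit of each
# support (shrinkage-free likelihood, so the criterion compares supports
# rather than shrunken fits).
path_refit_bic <- function(path, S, cvec, Xs, yc, w) {
  vapply(seq_len(ncol(path)), function(i) {
    sup <- which(path[, i] != 0)
    r <- if (length(sup)) {
      b <- tryCatch(solve(S[sup, sup, drop = FALSE], cvec[sup]),
                    error = function(e) path[sup, i])
      yc - drop(Xs[, sup, drop = FALSE] %*% b)
    } else yc
    weighted_bic(sum(w * r^2), w, length(sup))
  }, numeric(1))
}

#' Select the penalty weight on a grid
#'
#' Chooses lambda on a (given or data-driven) grid by minimizing either
#' the weighted BIC or the weighted k-fold cross-validation error.  The
#' BIC uses the Kish effective sample size `n_k = (sum w)^2 / sum(w^2)`
#' (the information content of a kernel-weighted fit; `n_k = n` for
#' uniform weights) and is evaluated on the weighted least-squares refit
#' of each candidate support, so supports rather than shrunken fits are
#' compared.  The path is solved with warm starts from the largest
#' lambda down.
#'
#' @inheritParams fit_penalized_regression
#' @param weights observation weights.
#' @return The selected lambda (scalar).
#' @export
select_lambda <- function(X, y, weights = NULL,
                          penalty = penalty_spec("lasso")) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  std <- weighted_standardize(X, y, weights)
  S <- crossprod(std$Xs, weights * std$Xs)
  cvec <- drop(crossprod(std$Xs, weights * std$yc))
  grid <- lambda_grid_for(cvec, penalty)
  if (length(grid) == 1L) return(grid)

  if (penalty$selection == "weighted_bic") {
    path <- gram_path(S, cvec, grid, penalty$gamma)
    crit <- path_refit_bic(path, S, cvec, std$Xs, std$yc, weights)
  } else {
    folds <- rep_len(seq_len(penalty$cv_folds), n)
    folds <- folds[order(order(y))]  # deterministic spread over the response
    crit <- numeric(length(grid))
    for (f in seq_len(penalty$cv_folds)) {
      hold <- folds == f
      if (all(hold) || !any(hold)) next
      stdf <- weighted_standardize(X[!hold, , drop = FALSE], y[!hold],
                                   weights[!hold])
      Sf <- crossprod(stdf$Xs, weights[!hold] * stdf$Xs)
      cf <- drop(crossprod(stdf$Xs, weights[!hold] * stdf$yc))
      pathf <- gram_path(Sf, cf, grid, penalty$gamma)
      for (i in seq_along(grid)) {
        beta <- pathf[, i] / stdf$xs
        b0 <- stdf$ym - sum(beta * stdf$xm)
        pred <- b0 + drop(X[hold, , drop = FALSE] %*% beta)
        crit[i] <- crit[i] + sum(weights[hold] * (y[hold] - pred)^2)
      }
    }
  }
  grid[which.min(crit)]
}

# Warm-started coefficient path on the standardized Gram form.
gram_path <- function(S, cvec, grid, gamma, tol = 1e-7, max_iter = 1e5L) {
  p <- length(cvec)
  out <- matrix(0, p, length(grid))
  b <- numeric(p)
  for (i in seq_along(grid)) {
    fit <- solve_gram(S, cvec, grid[i], gamma, beta0 = b, tol = tol,
                      max_iter = max_iter)
    b <- fit$beta
    out[, i] <- b
  }
  out
}
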