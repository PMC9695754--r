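#' Jaccard similarity between gene neighbourhoods
#'
#' For each pair of regulator genes, the Jaccard index of their
#' neighbour sets: `W_js = |N_j intersect N_s| / |N_j union N_s|`,
#' where `N_j` is the set of genes directly connected to gene j via an
#' edge in at least one sample's network.  Two empty sets have
#' similarity 0.
#'
#' @param neighbor_sets named list of character vectors, one per
#'   regulator gene.
#' @return An object of class `gene_similarity`: list with `W` (symmetric
#'   p x p matrix, entries in `[0, 1]`) and `neighbor_sets`.
#' @export
jaccard_similarity <- function(neighbor_sets) {
  p <- length(neighbor_sets)
  sets <- lapply(neighbor_sets, unique)
  ids <- names(sets)
  if (is.null(ids)) ids <- paste0("gene", seq_len(p))
  W <- matrix(0, p, p, dimnames = list(ids, ids))
  for (j in seq_len(p)) {
    if (length(sets[[j]])) W[j, j] <- 1
    for (s in seq_len(p)) {
      if (s <= j) next
      u <- length(union(sets[[j]], sets[[s]]))
      if (u == 0L) next
      W[j, s] <- W[s, j] <- length(intersect(sets[[j]], sets[[s]])) / u
    }
  }
  structure(list(W = W, neighbor_sets = sets), class = "gene_similarity")
}

#' Regulator neighbour sets of a sample-specific network
#'
#' `N_j` = all targets connected to regulator j by a nonzero coefficient
#' in at least one sample (undirected node sets).
#'
#' @param network a `sample_network`.
#' @return Named list of character vectors, one per regulator.
#' @export
neighbor_sets <- function(network) {
  stopifnot(inherits(network, "sample_network"))
  out <- stats::setNames(
    vector("list", length(network$regulator_ids)), network$regulator_ids)
  for (j in network$regulator_ids) out[[j]] <- character()
  e <- network$edges
  if (!is.null(e) && nrow(e)) {
    sp <- split(e$target, e$regulator)
    for (j in names(sp)) out[[j]] <- sort(unique(sp[[j]]))
  }
  out
}

# Weighted graph Laplacian of the off-diagonal similarity:
# theta' L theta = sum_{j<s} (theta_j - theta_s)^2 W_js.
similarity_laplacian <- function(W) {
  W0 <- W
  diag(W0) <- 0
  diag(rowSums(W0)) - W0
}

#' Gram matrix of a regulatory-effect set and its square root
#'
#' `G = sum_l R_l' R_l` and a symmetric positive semidefinite `Q` with
#' `Q'Q = G`, obtained by eigendecomposition with negative eigenvalues
#' clipped at zero.  Any `Q` with `Q'Q = G` yields the same G-dependent
#' quantities; the symmetric root is used for definiteness.
#'
#' @param effects a `regulatory_effects` object, or a list of n x p
#'   matrices.
#' @return An object of class `gram_factor`: list with `G`, `Q`,
#'   `eigenvalues`.
#' @export
gram_matrix <- function(effects) {
  mats <- if (inherits(effects, "regulatory_effects")) effects$matrices
          else effects
  stopifnot(length(mats) >= 1L)
  G <- Reduce(`+`, lapply(mats, function(R) {
    R <- as.matrix(R)
    if (any(!is.finite(R))) stop("non-finite entries in effect matrix")
    crossprod(R)
  }))
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  Q <- eg$vectors %*% (sqrt(ev) * t(eg$vectors))
  Q <- (Q + t(Q)) / 2
  dimnames(Q) <- dimnames(G)
  structure(list(G = G, Q = Q, eigenvalues = eg$values),
            class = "gram_factor")
}

#' Unpenalized common components
#'
#' The orthonormal `A` maximizing `tr(A'GA)` subject to `A'A = I_K`:
#' the top-K eigenvectors of `G` (equivalently, the PCA loadings of the
#' stacked effect matrices).
#'
#' @param G symmetric PSD p x p matrix (or a `gram_factor`).
#' @param K number of components, `1 <= K <= p`.
#' @return p x K orthonormal matrix, columns ordered by eigenvalue.
#' @export
common_components_unpenalized <- function(G, K) {
  if (inherits(G, "gram_factor")) G <- G$G
  p <- ncol(G)
  if (K < 1 || K > p) stop("'K' must be between 1 and p")
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  A <- eg$vectors[, seq_len(K), drop = FALSE]
  fix_column_signs(A)
}

# Deterministic sign: largest-magnitude entry of each column positive.
fix_column_signs <- function(A) {
  for (k in seq_len(ncol(A))) {
    i <- which.max(abs(A[, k]))
    if (A[i, k] < 0) A[, k] <- -A[, k]
  }
  A
}

#' Sparse network-fused loading update (theta step)
#'
#' Solves, for one component,
#' `min_theta ||z - Q theta||^2 + lambda1 ||theta||_1 +
#'  lambda2 sum_{j<s} (theta_j - theta_s)^2 W_js`.
#' The pairwise fusion term equals `lambda2 theta' L theta` with `L` the
#' weighted graph Laplacian of `W`, so the problem is an L1-penalized
#' quadratic solved by coordinate descent on the augmented Gram form.
#'
#' @param Q p x p matrix (square root of the Gram matrix).
#' @param z p-vector (typically `Q %*% a_k`).
#' @param W a `gene_similarity` object or symmetric p x p matrix.
#' @param lambda1 L1 penalty weight (sparsity).
#' @param lambda2 fusion penalty weight (network smoothing).
#' @param tol,max_iter coordinate-descent controls.
#' @return Numeric p-vector theta.
#' @export
theta_step <- function(Q, z, W, lambda1 = 0, lambda2 = 0,
                       tol = 1e-10, max_iter = 1e5L) {
  if (inherits(W, "gene_similarity")) W <- W$W
  Q <- as.matrix(Q)
  p <- ncol(Q)
  stopifnot(length(z) == nrow(Q), lambda1 >= 0, lambda2 >= 0)
  S <- 2 * crossprod(Q)
  if (lambda2 > 0) {
    if (!all(dim(W) == c(p, p))) stop("'W' must be p x p")
    S <- S + 2 * lambda2 * similarity_laplacian(W)
  }
  cvec <- 2 * drop(crossprod(Q, z))
  # guard a singular unpenalized system with a tiny ridge
  if (lambda1 == 0 && min(diag(S)) <= 0) diag(S) <- diag(S) + 1e-12
  fit <- cd_gram(S, cvec, lambda1, numeric(p), tol, as.integer(max_iter))
  fit$beta
}

#' Orthonormal factor update (A step)
#'
#' Procrustes update: given surrogate loadings `Theta`, the orthonormal
#' `A` maximizing `tr(A' Q'Q Theta)` is `U V'` from the thin SVD
#' `Q'Q Theta = U Gamma V'`.
#'
#' @param Q p x p matrix.
#' @param Theta p x K surrogate loading matrix.
#' @return p x K matrix with orthonormal columns.
#' @export
a_step <- function(Q, Theta) {
  Theta <- as.matrix(Theta)
  M <- crossprod(Q) %*% Theta
  sv <- svd(M)
  tol <- max(dim(M)) * max(sv$d, 0) * .Machine$double.eps
  if (any(sv$d <= tol))
    warning("rank-deficient Procrustes target; orthonormal factor completed from the SVD basis")
  sv$u %*% t(sv$v)
}

#' Network-constrained sparse common component analysis
#'
#' Extracts K sparse common loadings shared by the q regulatory-effect
#' matrices.  Starting from the unpenalized components (PCA of Q), it
#' alternates the sparse network-fused [theta_step()] (with
#' `z_k = Q a_k`) and the Procrustes [a_step()] until the relative
#' change in the column-normalized surrogate loadings falls below `tol`.
#' Final loadings are unit-normalized per column with a deterministic
#' sign (largest-magnitude entry positive).  With one effect matrix and
#' `lambda1 = lambda2 = 0` the procedure reduces to standard PCA.
#'
#' @param effects a `regulatory_effects` object, list of matrices, or a
#'   `gram_factor`.
#' @param W a `gene_similarity` (or matrix); may be `NULL` when
#'   `lambda2 = 0`.
#' @param K number of components; `"auto"` keeps enough unpenalized
#'   components to explain 80% of `trace(G)`.
#' @param lambda1,lambda2 sparsity and network-fusion penalty weights.
#' @param tol relative-change convergence tolerance on Theta.
#' @param max_iter maximum alternations.
#' @return An object of class `netscca`: list with `loadings` (p x K,
#'   unit columns; all-zero columns flagged in `zero_components`), `A`,
#'   `Theta`, `K`, `lambda1`, `lambda2`, `n_iter`, `converged`,
#'   `objective_trace` (the PCA objective `||Q - Q A A'||_F^2` per
#'   iteration).
#' @export
netscca_fit <- function(effects, W = NULL, K = "auto", lambda1 = 0,
                        lambda2 = 0, tol = 1e-4, max_iter = 200L) {
  gf <- if (inherits(effects, "gram_factor")) effects else gram_matrix(effects)
  if (tol <= 0) stop("'tol' must be positive")
  p <- ncol(gf$G)
  if (identical(K, "auto")) {
    ev <- pmax(gf$eigenvalues, 0)
    K <- which(cumsum(ev) / sum(ev) >= 0.8)[1L]
    if (is.na(K)) K <- 1L
  }
  if (K < 1 || K > p) stop("'K' must be between 1 and p")
  if (lambda2 > 0 && is.null(W))
    stop("'W' is required when lambda2 > 0")
  Wm <- if (is.null(W)) matrix(0, p, p)
        else if (inherits(W, "gene_similarity")) W$W else as.matrix(W)

  Q <- gf$Q
  A <- common_components_unpenalized(gf$G, K)
  normalize_cols <- function(M) {
    nn <- sqrt(colSums(M^2))
    nz <- nn > 0
    M[, nz] <- sweep(M[, nz, drop = FALSE], 2L, nn[nz], "/")
    M
  }
  obj <- function(A) sum(Q^2) - sum((Q %*% A)^2)  # ||Q - Q A A'||_F^2
  Theta_prev <- NULL
  trace_obj <- numeric(0)
  converged <- FALSE
  it <- 0L
  Theta <- A
  for (it in seq_len(max_iter)) {
    Z <- Q %*% A
    Theta <- vapply(seq_len(K), function(k)
      theta_step(Q, Z[, k], Wm, lambda1, lambda2), numeric(p))
    Theta <- matrix(Theta, p, K)
    if (all(colSums(Theta^2) == 0)) break  # penalty wiped everything out
    A <- a_step(Q, Theta)
    trace_obj <- c(trace_obj, obj(A))
    Tn <- normalize_cols(Theta)
    if (!is.null(Theta_prev)) {
      # sign-invariant relative change per column
      d <- vapply(seq_len(K), function(k) {
        min(sqrt(sum((Tn[, k] - Theta_prev[, k])^2)),
            sqrt(sum((Tn[, k] + Theta_prev[, k])^2)))
      }, numeric(1))
      if (max(d) < tol) { converged <- TRUE; break }
    }
    Theta_prev <- Tn
  }
  if (!converged && it == max_iter)
    warning("netscca_fit did not converge in max_iter alternations")

  nn <- sqrt(colSums(Theta^2))
  zero_components <- which(nn == 0)
  loadings <- Theta
  keep <- nn > 0
  loadings[, keep] <- sweep(Theta[, keep, drop = FALSE], 2L, nn[keep], "/")
  loadings <- fix_column_signs(loadings)
  dimnames(loadings) <- list(colnames(gf$G), paste0("component", seq_len(K)))
  structure(list(loadings = loadings, A = A, Theta = Theta, K = K,
                 lambda1 = lambda1, lambda2 = lambda2, n_iter = it,
                 converged = converged,
                 zero_components = zero_components,
                 objective_trace = trace_obj),
            class = "netscca")
}

#' @export
print.netscca <- function(x, ...) {
  cat(sprintf(
    "netscca: %d components over %d genes (lambda1 = %g, lambda2 = %g), %d iterations%s\n",
    x$K, nrow(x$loadings), x$lambda1, x$lambda2, x$n_iter,
    if (x$converged) "" else " (not converged)"))
  if (length(x$zero_components))
    cat("  all-zero components:", paste(x$zero_components, collapse = ", "),
        "\n")
  invisible(x)
}
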