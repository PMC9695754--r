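#' Regulatory-effect matrices
#'
#' Converts fitted sample-specific coefficients into regulatory effects
#' `r_{alpha l j} = beta_hat_jl(m_alpha) * x_{alpha j}`: the coefficient
#' times the regulator's expression in that sample.  One n x p matrix is
#' returned per target gene; effects inherit the sparsity pattern of the
#' coefficients.
#'
#' @param network a `sample_network` from [fit_sample_specific_network()].
#' @param panel the [expression_panel()] used to fit it.
#' @return An object of class `regulatory_effects`: list with `matrices`
#'   (length-q list of n x p matrices), and the aligned id vectors.
#' @export
regulatory_effects <- function(network, panel) {
  stopifnot(inherits(network, "sample_network"),
            inherits(panel, "expression_panel"))
  if (!identical(network$sample_ids, panel$sample_ids) ||
      !identical(network$regulator_ids, panel$regulator_ids) ||
      !identical(network$target_ids, panel$target_ids))
    stop("network and panel indexing do not align")
  A <- network_coef_array(network)
  q <- length(network$target_ids)
  mats <- lapply(seq_len(q), function(l) A[, , l] * panel$X)
  names(mats) <- network$target_ids
  structure(list(matrices = mats,
                 sample_ids = network$sample_ids,
                 regulator_ids = network$regulator_ids,
                 target_ids = network$target_ids),
            class = "regulatory_effects")
}

#' Construct a regulatory-effect set directly
#'
#' Low-level constructor used by the simulators and file readers.
#'
#' @param matrices list of q numeric n x p matrices.
#' @param sample_ids,regulator_ids,target_ids identifiers.
#' @return A `regulatory_effects` object.
#' @export
regulatory_effect_set <- function(matrices, sample_ids = NULL,
                                  regulator_ids = NULL, target_ids = NULL) {
  stopifnot(length(matrices) >= 1L)
  matrices <- lapply(matrices, as.matrix)
  n <- nrow(matrices[[1L]]); p <- ncol(matrices[[1L]])
  for (m in matrices) {
    if (nrow(m) != n || ncol(m) != p) stop("all matrices must be n x p")
    if (any(!is.finite(m))) stop("non-finite entries in effect matrix")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (is.null(regulator_ids)) regulator_ids <- paste0("regulator", seq_len(p))
  if (is.null(target_ids)) {
    target_ids <- names(matrices)
    if (is.null(target_ids)) target_ids <- paste0("target",
                                                  seq_along(matrices))
  }
  matrices <- lapply(matrices, function(m) {
    dimnames(m) <- list(sample_ids, regulator_ids); m
  })
  names(matrices) <- target_ids
  structure(list(matrices = matrices, sample_ids = sample_ids,
                 regulator_ids = regulator_ids, target_ids = target_ids),
            class = "regulatory_effects")
}

#' @export
print.regulatory_effects <- function(x, ...) {
  cat(sprintf("regulatory_effects: %d targets, each %d samples x %d regulators\n",
              length(x$matrices), length(x$sample_ids),
              length(x$regulator_ids)))
  invisible(x)
}

#' Per-sample edge list with effects
#'
#' Long-format table of all nonzero edges: one row per (sample,
#' regulator, target) with the fitted coefficient and the regulatory
#' effect (coefficient times expression).
#'
#' @inheritParams regulatory_effects
#' @return A data.frame with columns sample, regulator, target,
#'   coefficient, effect.
#' @export
edge_records <- function(network, panel) {
  e <- network$edges
  if (is.null(e) || !nrow(e))
    return(data.frame(sample = character(), regulator = character(),
                      target = character(), coefficient = numeric(),
                      effect = numeric(), stringsAsFactors = FALSE))
  x <- panel$X[cbind(match(e$sample, panel$sample_ids),
                     match(e$regulator, panel$regulator_ids))]
  data.frame(sample = e$sample, regulator = e$regulator, target = e$target,
             coefficient = e$beta, effect = e$beta * x,
             stringsAsFactors = FALSE)
}

#' Consensus edges over a sample subset
#'
#' Summarizes each (regulator, target) edge over a set of samples by the
#' median (default) or mean of its coefficients, taking the coefficient
#' as 0 in samples where the edge is absent.  Edges that are zero in
#' every subset sample are omitted.
#'
#' @param network a `sample_network`.
#' @param sample_subset sample ids or indices (default: all samples).
#' @param statistic `"median"` (default, as used for consensus network
#'   summaries) or `"mean"`.
#' @return A data.frame with columns regulator, target,
#'   median_coefficient (or mean_coefficient), n_nonzero_samples.
#' @export
consensus_edges <- function(network, sample_subset = NULL,
                            statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(network, "sample_network"))
  if (is.null(sample_subset)) sample_subset <- network$sample_ids
  if (is.numeric(sample_subset))
    sample_subset <- network$sample_ids[sample_subset]
  if (!length(sample_subset)) stop("'sample_subset' must be nonempty")
  if (!all(sample_subset %in% network$sample_ids))
    stop("unknown sample id in 'sample_subset'")
  e <- network$edges
  e <- e[e$sample %in% sample_subset, , drop = FALSE]
  if (is.null(e) || !nrow(e))
    return(data.frame(regulator = character(), target = character(),
                      value = numeric(), n_nonzero_samples = integer()))
  key <- paste(e$regulator, e$target, sep = "\r")
  ns <- length(sample_subset)
  fun <- if (statistic == "median") stats::median else mean
  agg <- lapply(split(seq_len(nrow(e)), key), function(idx) {
    betas <- c(e$beta[idx], rep(0, ns - length(idx)))  # absent edges are 0
    data.frame(regulator = e$regulator[idx[1L]], target = e$target[idx[1L]],
               value = fun(betas), n_nonzero_samples = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  names(out)[names(out) == "value"] <- paste0(statistic, "_coefficient")
  rownames(out) <- NULL
  out[order(out$target, out$regulator), , drop = FALSE]
}
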