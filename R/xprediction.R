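#' Percentile-based sensitive/resistant labeling
#'
#' Labels samples whose drug sensitivity is strictly below the `low_p`-th
#' percentile as sensitive (label 1) and strictly above the `high_p`-th
#' percentile as resistant (label 0); samples in between are excluded.
#' Percentiles use linear interpolation (`stats::quantile` type 7), so
#' at small n the labeled sets are sensitive to the interpolation rule.
#'
#' @param sensitivity numeric drug-sensitivity vector (named or not).
#' @param low_p,high_p percentile cut points (defaults 5 and 95).
#' @return A list with `labels` (named 0/1 vector over labeled samples),
#'   `sensitive`, `resistant`, `excluded` (index vectors), and the two
#'   percentile values.
#' @export
label_by_percentile <- function(sensitivity, low_p = 5, high_p = 95) {
  if (low_p >= high_p) stop("'low_p' must be below 'high_p'")
  s <- as.numeric(sensitivity)
  qs <- stats::quantile(s, c(low_p, high_p) / 100, names = FALSE, type = 7)
  sensitive <- which(s < qs[1L])
  resistant <- which(s > qs[2L])
  if (length(sensitive) < 2L || length(resistant) < 2L)
    stop("degenerate labeling: fewer than 2 samples in a class")
  labeled <- sort(c(sensitive, resistant))
  labels <- as.integer(labeled %in% sensitive)
  nm <- names(sensitivity)
  if (!is.null(nm)) names(labels) <- nm[labeled]
  list(labels = labels, sensitive = sensitive, resistant = resistant,
       excluded = setdiff(seq_along(s), labeled),
       low_cut = qs[1L], high_cut = qs[2L])
}

#' Edge-feature matrix for labeled samples
#'
#' Flattens a regulatory-effect set into a samples x edges feature
#' matrix, keeping the edges (target, regulator) whose effect is nonzero
#' in at least one sample, restricted to the labeled samples.
#'
#' @param effects a `regulatory_effects` object.
#' @param labeling result of [label_by_percentile()], or a 0/1 vector
#'   over all samples with `NA` for excluded ones.
#' @return An object of class `labeled_effects`: list with `features`
#'   (n_labeled x E matrix), `labels`, `edge_index` (data.frame target,
#'   regulator), `excluded_samples`.
#' @export
labeled_effects <- function(effects, labeling) {
  stopifnot(inherits(effects, "regulatory_effects"))
  n <- length(effects$sample_ids)
  if (is.list(labeling)) {
    keep <- sort(c(labeling$sensitive, labeling$resistant))
    labels <- as.integer(keep %in% labeling$sensitive)
    excluded <- labeling$excluded
  } else {
    keep <- which(!is.na(labeling))
    labels <- as.integer(labeling[keep])
    excluded <- which(is.na(labeling))
  }
  cols <- list(); idx <- list()
  for (l in seq_along(effects$matrices)) {
    R <- effects$matrices[[l]]
    nz <- which(colSums(R != 0) > 0)
    if (!length(nz)) next
    cols[[length(cols) + 1L]] <- R[keep, nz, drop = FALSE]
    idx[[length(idx) + 1L]] <- data.frame(
      target = effects$target_ids[l],
      regulator = effects$regulator_ids[nz],
      stringsAsFactors = FALSE)
  }
  if (!length(cols)) stop("no edge is nonzero in any sample")
  features <- do.call(cbind, cols)
  edge_index <- do.call(rbind, idx)
  colnames(features) <- paste(edge_index$regulator, edge_index$target,
                              sep = "->")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  structure(list(features = features, labels = labels,
                 edge_index = edge_index,
                 excluded_samples = effects$sample_ids[excluded]),
            class = "labeled_effects")
}

#' Predictor specification for edge-knockout importance
#'
#' @param model `"random_forest"`, `"kernel_svm"` or `"feedforward_nn"`.
#' @param k cross-validation folds (default 10).
#' @param N repeats of the k-fold CV with freshly randomized folds.
#' @param seed base RNG seed; all fold splits and model fits derive from
#'   it deterministically.
#' @param hyperparameters named list per model: `num.trees` (random
#'   forest), `cost`/`gamma` (kernel SVM), `hidden`/`epochs`/`lr`
#'   (feed-forward net, default two hidden layers of 64 and 32 units).
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(model = c("feedforward_nn", "random_forest",
                                     "kernel_svm"),
                           k = 10L, N = 20L, seed = 1L,
                           hyperparameters = list()) {
  model <- match.arg(model)
  if (k < 2L) stop("'k' must be at least 2")
  if (N < 2L) stop("'N' must be at least 2")
  defaults <- switch(model,
    random_forest = list(num.trees = 100L),
    kernel_svm = list(cost = 1, gamma = NULL),
    feedforward_nn = list(hidden = c(64L, 32L), epochs = 300L, lr = 0.01))
  hyperparameters <- utils::modifyList(defaults, hyperparameters)
  structure(list(model = model, k = as.integer(k), N = as.integer(N),
                 seed = as.integer(seed), hyperparameters = hyperparameters),
            class = "predictor_spec")
}

train_and_classify <- function(model, hp, xtr, ytr, xte, fit_seed) {
  if (model == "random_forest") {
    fit <- ranger::ranger(x = as.data.frame(xtr), y = factor(ytr,
                          levels = c(0, 1)),
                          num.trees = hp$num.trees, seed = fit_seed,
                          num.threads = 1L)
    as.integer(as.character(
      stats::predict(fit, data = as.data.frame(xte),
                     num.threads = 1L)$predictions))
  } else if (model == "kernel_svm") {
    ctr <- colMeans(xtr)
    scl <- apply(xtr, 2L, stats::sd); scl[scl < 1e-12] <- 1
    Ztr <- sweep(sweep(xtr, 2L, ctr), 2L, scl, "/")
    Zte <- sweep(sweep(xte, 2L, ctr), 2L, scl, "/")
    g <- if (is.null(hp$gamma)) 1 / ncol(xtr) else hp$gamma
    fit <- e1071::svm(Ztr, factor(ytr, levels = c(0, 1)),
                      kernel = "radial", cost = hp$cost, gamma = g,
                      scale = FALSE)
    as.integer(as.character(stats::predict(fit, Zte)))
  } else {
    set.seed(fit_seed)
    fit <- mlp_fit(xtr, ytr, hidden = hp$hidden, epochs = hp$epochs,
                   lr = hp$lr)
    predict(fit, xte)
  }
}

stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    folds[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  folds
}

#' Repeated cross-validated prediction accuracy
#'
#' Runs N repeats of stratified k-fold cross-validation; each repeat's
#' accuracy is the mean over its k validation folds of the fraction of
#' correctly classified samples.  Fold splits and model training are
#' fully determined by the spec's seed.
#'
#' @param data a `labeled_effects` object.
#' @param spec a [predictor_spec()].
#' @param seed_offset internal offset so knockout runs use fresh fold
#'   seeds while staying deterministic.
#' @return An object of class `accuracy_record`: list with `accuracies`
#'   (length N), `mean`, `sd`, `N`.
#' @export
cv_accuracy <- function(data, spec, seed_offset = 0L) {
  stopifnot(inherits(data, "labeled_effects"),
            inherits(spec, "predictor_spec"))
  y <- data$labels
  x <- data$features
  if (min(table(y)) < spec$k)
    stop("each class needs at least k members for stratified k-fold CV")
  acc <- numeric(spec$N)
  for (r in seq_len(spec$N)) {
    rs <- (spec$seed + seed_offset + 7919L * (r - 1L)) %% .Machine$integer.max
    set.seed(rs)
    folds <- stratified_folds(y, spec$k)
    fold_acc <- numeric(spec$k)
    for (f in seq_len(spec$k)) {
      te <- folds == f
      pred <- train_and_classify(spec$model, spec$hyperparameters,
                                 x[!te, , drop = FALSE], y[!te],
                                 x[te, , drop = FALSE],
                                 fit_seed = rs + f)
      fold_acc[f] <- mean(pred == y[te])
    }
    acc[r] <- mean(fold_acc)
  }
  structure(list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
                 N = spec$N),
            class = "accuracy_record")
}

#' Accuracy after removing one edge's features
#'
#' Deletes the feature column of edge (target, regulator) and re-runs
#' the repeated cross-validation with fresh fold seeds.
#'
#' @inheritParams cv_accuracy
#' @param edge length-2 character vector `c(target, regulator)`, or the
#'   edge's row index in `data$edge_index`.
#' @return An `accuracy_record`.
#' @export
knockout_accuracy <- function(data, spec, edge) {
  ei <- data$edge_index
  pos <- if (is.numeric(edge)) as.integer(edge)
         else which(ei$target == edge[1L] & ei$regulator == edge[2L])
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > nrow(ei))
    stop("unknown edge")
  if (ncol(data$features) <= 1L)
    stop("cannot remove the only feature column")
  d2 <- data
  d2$features <- data$features[, -pos, drop = FALSE]
  d2$edge_index <- ei[-pos, , drop = FALSE]
  cv_accuracy(d2, spec, seed_offset = 104729L * pos)
}

#' Pooled two-sample t-test between accuracy records
#'
#' `T = (mean_full - mean_knockout) / (s_p * sqrt(1/N + 1/N'))` with
#' `s_p` the pooled standard deviation
#' `sqrt(((N-1) s^2 + (N'-1) s'^2) / (N + N' - 2))` and a two-sided p
#' value on `N + N' - 2` degrees of freedom.  `pooled = "as_printed"`
#' instead uses `(s (N-1) + s' (N'-1)) / (N + N' - 2)` without squares
#' or square root, for comparison with the non-standard printed form.
#'
#' @param full,knockout `accuracy_record` objects.
#' @param pooled `"standard"` (default) or `"as_printed"`.
#' @return A list with `T`, `p`, `df`, `mean_drop`.
#' @export
pooled_t_test <- function(full, knockout,
                          pooled = c("standard", "as_printed")) {
  pooled <- match.arg(pooled)
  N1 <- full$N; N2 <- knockout$N
  if (N1 < 2L || N2 < 2L) stop("both records need at least 2 repeats")
  df <- N1 + N2 - 2
  sp <- if (pooled == "standard")
    sqrt(((N1 - 1) * full$sd^2 + (N2 - 1) * knockout$sd^2) / df)
  else (full$sd * (N1 - 1) + knockout$sd * (N2 - 1)) / df
  drop_ <- full$mean - knockout$mean
  if (sp == 0) {
    if (drop_ == 0) return(list(T = 0, p = 1, df = df, mean_drop = 0))
    return(list(T = sign(drop_) * Inf, p = 0, df = df, mean_drop = drop_))
  }
  Tstat <- drop_ / (sp * sqrt(1 / N1 + 1 / N2))
  list(T = Tstat, p = 2 * stats::pt(-abs(Tstat), df), df = df,
       mean_drop = drop_)
}

#' Edge-knockout explainable prediction
#'
#' Ranks regulator-target interactions by how much removing each edge's
#' feature column degrades the cross-validated prediction of a binary
#' drug response.  Samples are labeled sensitive/resistant by sensitivity
#' percentiles, a baseline repeated-CV accuracy is computed once, and
#' every candidate edge is knocked out in turn and compared with the
#' baseline by a pooled t-test.  The per-edge cost is one full
#' repeated-CV model stack, so E edges cost E + 1 model stacks.
#'
#' @param effects a `regulatory_effects` object.
#' @param sensitivity numeric drug-sensitivity vector over all samples.
#' @param spec a [predictor_spec()].
#' @param alpha raw significance level for the `significant` flag.
#' @param edge_subset optional data.frame (target, regulator) restricting
#'   which edges are knocked out.
#' @param low_p,high_p labeling percentiles.
#' @param adjust add a Benjamini-Hochberg adjusted column `p_adj`.
#' @return An object of class `edge_importance`: data.frame with columns
#'   target, regulator, T, p, mean_drop, significant (and `p_adj` when
#'   requested), sorted by p ascending; baseline record in
#'   `attr(, "baseline")`.
#' @export
xprediction <- function(effects, sensitivity, spec = predictor_spec(),
                        alpha = 0.05, edge_subset = NULL,
                        low_p = 5, high_p = 95, adjust = FALSE) {
  lab <- label_by_percentile(sensitivity, low_p, high_p)
  data <- labeled_effects(effects, lab)
  ei <- data$edge_index
  test_rows <- seq_len(nrow(ei))
  if (!is.null(edge_subset)) {
    test_rows <- match(paste(edge_subset$target, edge_subset$regulator),
                       paste(ei$target, ei$regulator))
    if (anyNA(test_rows)) stop("edge_subset contains unknown edges")
  }
  if (!length(test_rows)) stop("no candidate edge to test")
  baseline <- cv_accuracy(data, spec)
  rows <- lapply(test_rows, function(pos) {
    ko <- knockout_accuracy(data, spec, pos)
    tt <- pooled_t_test(baseline, ko)
    data.frame(target = ei$target[pos], regulator = ei$regulator[pos],
               T = tt$T, p = tt$p, mean_drop = tt$mean_drop,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, -abs(out$T)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  class(out) <- c("edge_importance", "data.frame")
  out
}
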