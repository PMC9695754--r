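#' Validate a pipeline configuration
#'
#' A configuration is a named list (or JSON file) with blocks:
#' `expression` (path, samples x genes), `modulator` (path), optional
#' `targets` (path; defaults to the expression file), `output_dir`,
#' `seed`, `top_fraction`, and parameter blocks `kernel`, `penalty`,
#' `netscca` (with `enabled`), `xprediction` (with `enabled`,
#' `sensitivity_column`).  Unknown keys are rejected; referenced input
#' paths must exist.
#'
#' @param config named list or path to a JSON file.
#' @return The validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  known <- c("expression", "targets", "modulator", "output_dir", "seed",
             "top_fraction", "kernel", "penalty", "netscca", "xprediction",
             "log_level")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  for (key in c("expression", "modulator")) {
    if (is.null(config[[key]])) stop(sprintf("config is missing '%s'", key))
    if (!file.exists(config[[key]]))
      stop(sprintf("'%s' path does not exist: %s", key, config[[key]]))
  }
  if (!is.null(config$targets) && !file.exists(config$targets))
    stop(sprintf("'targets' path does not exist: %s", config$targets))
  if (is.null(config$output_dir)) stop("config is missing 'output_dir'")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$top_fraction)) config$top_fraction <- 1
  defaults <- list(
    kernel = list(mode = "adaptive_knn"),
    penalty = list(family = "lasso", lambda = "auto"),
    netscca = list(enabled = TRUE, K = "auto", lambda1 = 0, lambda2 = 0),
    xprediction = list(enabled = TRUE, model = "feedforward_nn", k = 10L,
                       N = 20L, alpha = 0.05, low_p = 5, high_p = 95,
                       sensitivity_column = 1L))
  for (blk in names(defaults))
    config[[blk]] <- utils::modifyList(defaults[[blk]],
                                       as.list(config[[blk]]))
  structure(config, class = "pipeline_config")
}

kernel_from_block <- function(blk) {
  kernel_config(mode = blk$mode,
                bandwidth = blk$bandwidth,
                k = blk$k,
                range_factor = if (is.null(blk$range_factor)) "auto"
                               else blk$range_factor,
                bandwidth_matrix = if (is.null(blk$bandwidth_matrix)) "auto"
                                   else blk$bandwidth_matrix)
}

penalty_from_block <- function(blk) {
  penalty_spec(family = blk$family,
               lambda = if (is.null(blk$lambda)) "auto" else blk$lambda,
               gamma = blk$gamma,
               lambda_grid = blk$lambda_grid,
               n_lambda = if (is.null(blk$n_lambda)) 20L else blk$n_lambda)
}

#' Run the full pipeline
#'
#' Variance-filters the expression, fits the sample-specific network,
#' derives regulatory effects, optionally extracts sparse common
#' loadings, optionally ranks edges by knockout importance against the
#' first modulator characteristic, and writes all outputs plus a run
#' manifest to the output directory.  Stage failures abort with the
#' stage name; outputs of completed stages are kept.
#'
#' @param config a [pipeline_config()] (or list / JSON path coercible to
#'   one).
#' @return Invisibly, a list of output file paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$output_dir, f)
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  inputs <- stage("read_inputs", {
    X <- read_expression_table(config$expression)
    Y <- if (is.null(config$targets)) X
         else read_expression_table(config$targets)
    mods <- read_modulator_table(config$modulator)
    list(X = X, Y = Y, mods = mods)
  })

  filtered <- stage("variance_filter", {
    keepX <- variance_filter(inputs$X, config$top_fraction)
    keepY <- variance_filter(inputs$Y, config$top_fraction)
    expression_panel(inputs$X[, keepX, drop = FALSE],
                     inputs$Y[, keepY, drop = FALSE])
  })

  network <- stage("fit_network", {
    set.seed(config$seed)
    fit_sample_specific_network(filtered, inputs$mods,
                                kernel_from_block(config$kernel),
                                penalty_from_block(config$penalty))
  })

  effects <- stage("regulatory_effects", {
    eff <- regulatory_effects(network, filtered)
    edges <- edge_records(network, filtered)
    write_edge_list(edges, outp("edges.tsv"))
    cons <- consensus_edges(network)
    cons$median_coefficient <- sprintf("%.17g", cons$median_coefficient)
    write_table_tsv(cons, outp("consensus_edges.tsv"))
    eff
  })
  outputs$edges <- outp("edges.tsv")
  outputs$consensus <- outp("consensus_edges.tsv")

  if (isTRUE(config$netscca$enabled)) {
    stage("netscca", {
      W <- jaccard_similarity(neighbor_sets(network))
      fit <- netscca_fit(effects, W, K = config$netscca$K,
                         lambda1 = config$netscca$lambda1,
                         lambda2 = config$netscca$lambda2)
      write_matrix_tsv(fit$loadings, outp("loadings.tsv"), "regulator")
    })
    outputs$loadings <- outp("loadings.tsv")
  }

  if (isTRUE(config$xprediction$enabled)) {
    stage("xprediction", {
      xb <- config$xprediction
      sens <- inputs$mods$values[, xb$sensitivity_column]
      names(sens) <- inputs$mods$sample_ids
      spec <- predictor_spec(model = xb$model, k = xb$k, N = xb$N,
                             seed = config$seed)
      imp <- xprediction(effects, sens, spec, alpha = xb$alpha,
                         low_p = xb$low_p, high_p = xb$high_p)
      out <- as.data.frame(imp)
      for (cl in c("T", "p", "mean_drop"))
        out[[cl]] <- sprintf("%.17g", out[[cl]])
      write_table_tsv(out, outp("edge_importance.tsv"))
    })
    outputs$importance <- outp("edge_importance.tsv")
  }

  manifest <- list(
    package = "profnet",
    version = as.character(utils::packageVersion("profnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    outputs = outputs)
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  outputs$manifest <- outp("manifest.json")
  invisible(outputs)
}

#' Write simulated pipeline inputs to disk
#'
#' Generates a varying-coefficient dataset and writes the expression,
#' target and modulator TSVs plus a JSON ground-truth summary, ready for
#' [run_pipeline()].
#'
#' @param dir output directory.
#' @param n,p,q,seed passed to [simulate_varying_network()].
#' @return Invisibly, the list of file paths.
#' @export
write_simulated_inputs <- function(dir, n = 100L, p = 10L, q = 5L,
                                   seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_varying_network(n = n, p = p, q = q, seed = seed)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                targets = file.path(dir, "targets.tsv"),
                modulator = file.path(dir, "modulator.tsv"),
                truth = file.path(dir, "truth.json"))
  write_matrix_tsv(sim$panel$X, paths$expression, "sample")
  write_matrix_tsv(sim$panel$Y, paths$targets, "sample")
  write_matrix_tsv(sim$modulators$values, paths$modulator, "sample")
  nz <- which(sim$truth$beta != 0, arr.ind = TRUE)
  jsonlite::write_json(
    list(seed = seed, n = n, p = p, q = q,
         noise_sd = sim$truth$noise_sd,
         nonzero_true_coefficients = nrow(nz)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
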