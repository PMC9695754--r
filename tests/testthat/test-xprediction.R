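# build a labeled_effects object directly from a feature matrix
manual_labeled <- function(x, y) {
  E <- ncol(x)
  structure(list(
    features = x, labels = as.integer(y),
    edge_index = data.frame(target = paste0("t", seq_len(E)),
                            regulator = paste0("r", seq_len(E)),
                            stringsAsFactors = FALSE),
    excluded_samples = character()), class = "labeled_effects")
}

two_clouds <- function(n = 60, E = 4, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * E), n, E)
  x[, 1] <- x[, 1] + sep * y
  manual_labeled(x, y)
}

test_that("percentile labeling uses strict cuts with interpolated percentiles", {
  lab <- label_by_percentile(1:100)
  expect_equal(lab$sensitive, 1:5)       # values < 5.95
  expect_equal(lab$resistant, 96:100)    # values > 95.05
  expect_equal(sum(lab$labels), 5L)
  expect_equal(length(lab$excluded), 90L)
  expect_equal(lab$low_cut, unname(quantile(1:100, 0.05)))
  expect_error(label_by_percentile(rep(3, 50)), "degenerate")
  expect_error(label_by_percentile(1:100, 0, 100), "degenerate")
  expect_error(label_by_percentile(1:100, 80, 20), "below")
})

test_that("labeled_effects keeps edges nonzero in at least one sample", {
  mats <- list(t1 = cbind(a = c(1, 0, 2, 0), b = rep(0, 4)),
               t2 = cbind(a = rep(0, 4), b = c(0, 3, 0, 1)))
  eff <- regulatory_effect_set(mats, sample_ids = paste0("s", 1:4),
                               regulator_ids = c("a", "b"))
  labeling <- c(1, 0, NA, 1)
  d <- labeled_effects(eff, labeling)
  expect_equal(ncol(d$features), 2L)  # zero columns dropped
  expect_equal(d$edge_index$regulator, c("a", "b"))
  expect_equal(d$edge_index$target, c("t1", "t2"))
  expect_equal(nrow(d$features), 3L)
  expect_equal(d$excluded_samples, "s3")
})

test_that("separable classes are predicted accurately by all three models", {
  d <- two_clouds()
  for (model in c("random_forest", "kernel_svm", "feedforward_nn")) {
    hp <- if (model == "feedforward_nn")
      list(hidden = c(16L, 8L), epochs = 150L) else list()
    spec <- predictor_spec(model, k = 5, N = 3, seed = 11,
                           hyperparameters = hp)
    rec <- cv_accuracy(d, spec)
    expect_gte(rec$mean, 0.95)
    expect_true(all(rec$accuracies >= 0 & rec$accuracies <= 1))
  }
})

test_that("repeated CV is deterministic under a fixed seed", {
  d <- two_clouds(seed = 2, sep = 1.2)  # overlapping, so accuracy varies
  spec <- predictor_spec("random_forest", k = 5, N = 4, seed = 3,
                         hyperparameters = list(num.trees = 50))
  r1 <- cv_accuracy(d, spec)
  r2 <- cv_accuracy(d, spec)
  expect_identical(r1$accuracies, r2$accuracies)
  # different seed gives different folds
  r3 <- cv_accuracy(d, predictor_spec("random_forest", k = 5, N = 4,
                                      seed = 4,
                                      hyperparameters = list(num.trees = 50)))
  expect_false(identical(r1$accuracies, r3$accuracies))
})

test_that("permuted labels predict at chance level", {
  set.seed(5)
  d <- two_clouds(n = 80, seed = 5)
  d$labels <- sample(d$labels)
  spec <- predictor_spec("random_forest", k = 5, N = 20, seed = 7,
                         hyperparameters = list(num.trees = 50))
  rec <- cv_accuracy(d, spec)
  expect_lt(abs(rec$mean - 0.5), 3 * max(rec$sd, 0.02))
})

test_that("knocking out an uninformative feature does not move accuracy", {
  d <- two_clouds(n = 80, E = 5, seed = 9)  # columns 2..5 pure noise
  spec <- predictor_spec("random_forest", k = 5, N = 20, seed = 13,
                         hyperparameters = list(num.trees = 50))
  base <- cv_accuracy(d, spec)
  ko <- knockout_accuracy(d, spec, c("t3", "r3"))
  tt <- pooled_t_test(base, ko)
  expect_lt(abs(tt$T), 6)
})

test_that("knocking out the sole predictive feature collapses accuracy", {
  d <- two_clouds(n = 80, E = 5, sep = 5, seed = 10)
  spec <- predictor_spec("random_forest", k = 5, N = 8, seed = 17,
                         hyperparameters = list(num.trees = 50))
  base <- cv_accuracy(d, spec)
  ko <- knockout_accuracy(d, spec, 1L)
  expect_gte(base$mean - ko$mean, 0.2)
  expect_error(knockout_accuracy(d, spec, c("t9", "r9")), "unknown edge")
  d1 <- manual_labeled(d$features[, 1, drop = FALSE], d$labels)
  expect_error(knockout_accuracy(d1, spec, 1L), "only feature")
})

test_that("the pooled t-test matches its closed form and symmetries", {
  rec <- function(mean, sd, N) structure(list(mean = mean, sd = sd, N = N),
                                         class = "accuracy_record")
  tt <- pooled_t_test(rec(0.9, 0.05, 10), rec(0.8, 0.05, 10))
  expect_equal(tt$T, 0.1 / (0.05 * sqrt(0.2)), tolerance = 1e-12)
  expect_equal(tt$T, 4.47213595, tolerance = 1e-6)
  expect_equal(tt$df, 18)
  expect_equal(tt$p, 2 * pt(-abs(tt$T), 18))
  # antisymmetry
  rev <- pooled_t_test(rec(0.8, 0.05, 10), rec(0.9, 0.05, 10))
  expect_equal(rev$T, -tt$T)
  expect_equal(rev$p, tt$p)
  # degenerate pooled sd
  expect_equal(pooled_t_test(rec(0.7, 0, 5), rec(0.7, 0, 5))$p, 1)
  z <- pooled_t_test(rec(0.8, 0, 5), rec(0.7, 0, 5))
  expect_identical(z$T, Inf)
  expect_identical(z$p, 0)
  # the as-printed variant differs unless sd = 0
  tp <- pooled_t_test(rec(0.9, 0.05, 10), rec(0.8, 0.03, 10),
                      pooled = "as_printed")
  ts <- pooled_t_test(rec(0.9, 0.05, 10), rec(0.8, 0.03, 10))
  expect_false(isTRUE(all.equal(tp$T, ts$T)))
})

test_that("larger |T| always means smaller p at fixed df", {
  recs <- lapply(seq(0, 0.15, by = 0.05), function(d)
    pooled_t_test(structure(list(mean = 0.8 + d, sd = 0.05, N = 10),
                            class = "accuracy_record"),
                  structure(list(mean = 0.8, sd = 0.05, N = 10),
                            class = "accuracy_record")))
  Ts <- sapply(recs, `[[`, "T")
  ps <- sapply(recs, `[[`, "p")
  expect_true(all(diff(abs(Ts)) > 0))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("xprediction ranks a causal edge first and respects subsets", {
  sim <- simulate_common_structure(q = 2, n = 400, p = 6, K = 1,
                                   support_size = 3, noise_sd = 0.3,
                                   seed = 19)
  causal <- data.frame(target = "target1", regulator = "G001")
  sens <- simulate_drug_response(sim$effects, causal, 4, noise_sd = 0.3,
                                 seed = 19)
  spec <- predictor_spec("random_forest", k = 5, N = 5, seed = 23,
                         hyperparameters = list(num.trees = 50))
  imp <- xprediction(sim$effects, sens, spec, low_p = 20, high_p = 80)
  expect_s3_class(imp, "edge_importance")
  expect_true(all(imp$p >= 0 & imp$p <= 1))
  expect_true(!is.unsorted(imp$p))
  expect_equal(imp$target[1], "target1")
  expect_equal(imp$regulator[1], "G001")
  # determinism of the full procedure
  imp2 <- xprediction(sim$effects, sens, spec, low_p = 20, high_p = 80)
  expect_identical(as.data.frame(imp), as.data.frame(imp2))
  # single-edge subset
  imp1 <- xprediction(sim$effects, sens, spec, low_p = 20, high_p = 80,
                      edge_subset = causal)
  expect_equal(nrow(imp1), 1L)
  # BH adjustment behind the flag
  impadj <- xprediction(sim$effects, sens, spec, low_p = 20, high_p = 80,
                        adjust = TRUE)
  expect_true(all(impadj$p_adj >= impadj$p - 1e-12))
})
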