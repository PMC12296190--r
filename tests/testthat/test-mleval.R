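test_that("stratified splits preserve class balance and are reproducible", {
  set.seed(1)
  labels <- c(rep(1L, 29), rep(0L, 71))[sample(100)]
  sp <- split_indices(labels, "holdout_90_10", seed = 2)
  expect_length(sp$eval, 10L)
  expect_true(abs(sum(labels[sp$eval]) - 3L) <= 1L)
  expect_identical(sort(c(sp$train, sp$eval)), 1:100)
  expect_identical(split_indices(labels, "holdout_90_10", seed = 2), sp)
  expect_false(identical(split_indices(labels, "holdout_90_10", seed = 3),
                         sp))

  sp5 <- split_indices(labels, "holdout_95_5", seed = 2)
  expect_length(sp5$eval, 5L)

  folds <- split_indices(labels, "skf", k = 10, seed = 2)
  evals <- unlist(lapply(folds, `[[`, "eval"))
  expect_identical(sort(evals), 1:100)      # each row in exactly one fold
  pos_per_fold <- vapply(folds, function(f) sum(labels[f$eval]), integer(1))
  expect_true(max(pos_per_fold) - min(pos_per_fold) <= 1L)

  expect_error(split_indices(rep(1L, 10)), "both classes")
})

test_that("AUPRC matches brute-force PR-curve oracles", {
  set.seed(4)
  for (k in 1:10) {
    n <- sample(20:100, 1)
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) labels[1] <- 1L
    scores <- rnorm(n) + 0.8 * labels
    # exact against the brute-force step-wise (average precision) definition
    expect_equal(auprc(scores, labels),
                 brute_average_precision(scores, labels), tolerance = 1e-12)
    # close to the trapezoidal integral (a different standard estimator)
    expect_lt(abs(auprc(scores, labels) - trapezoid_auprc(scores, labels)),
              0.1)
  }
  # perfectly ranked scores: both estimators give exactly 1
  lab <- rep(c(1L, 0L), c(10, 30))
  sc <- seq(1, 0, length.out = 40)
  expect_equal(auprc(sc, lab), 1)
  expect_equal(trapezoid_auprc(sc, lab), 1)
  # perfectly anti-ranked positives at the bottom
  expect_lt(auprc(-sc, lab), 0.3)
})

test_that("AUPRC handles ties by grouping thresholds", {
  # all scores tied: precision = prevalence at the single threshold
  expect_equal(auprc(rep(0.5, 10), rep(c(1L, 0L), c(3, 7))), 0.3)
  curve <- pr_curve(c(0.9, 0.9, 0.1), c(1L, 0L, 1L))
  expect_identical(nrow(curve), 2L)
})

test_that("label-independent scores give AUPRC near the prevalence", {
  set.seed(0)
  aps <- vapply(1:20, function(s) {
    set.seed(s)
    auprc(runif(500), rbinom(500, 1, 0.29))
  }, numeric(1))
  expect_lt(abs(mean(aps) - 0.29), 0.05)
})

test_that("confusion metrics are internally consistent and NA-safe", {
  m <- confusion_metrics(tp = 497, fp = 267, tn = 308, fn = 268)
  expect_equal(m$precision, 497 / (497 + 267))
  expect_equal(m$recall, 497 / (497 + 268))
  expect_equal(m$specificity, 308 / (308 + 267))
  expect_equal(m$accuracy, (497 + 308) / 1340)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_equal(m$tp_fp_ratio, 497 / 267)

  # all-negative predictor: precision undefined, accuracy = negative
  # prevalence, TP/FP ratio undefined
  deg <- confusion_metrics(tp = 0, fp = 0, tn = 71, fn = 29)
  expect_true(is.na(deg$precision))
  expect_true(is.na(deg$tp_fp_ratio))
  expect_equal(deg$accuracy, 0.71)
})

make_separable_table <- function(n = 200, seed = 9) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)[sample(n)]
  feature_table(data.frame(signal = y + rnorm(n, sd = 0.05),
                           noise1 = rnorm(n), noise2 = rnorm(n)), y)
}

test_that("all learners separate a separable problem perfectly", {
  ft <- make_separable_table()
  for (model in c("gradient_boosted_trees", "knn", "random_forest")) {
    r <- evaluate_model(ft, model, scheme = "holdout_90_10", seed = 4)
    expect_equal(r$auprc, 1, label = model)
    expect_equal(r$f1, 1, label = model)
    # counts always sum to the evaluation-set size and reproduce the rates
    expect_identical(r$tp + r$fp + r$tn + r$fn, r$n_eval)
    expect_equal(r$precision, r$tp / (r$tp + r$fp))
  }
})

test_that("evaluation reports are seed-deterministic", {
  ft <- make_separable_table()
  a <- evaluate_model(ft, "random_forest", seed = 7)
  b <- evaluate_model(ft, "random_forest", seed = 7)
  expect_identical(a, b)
})

test_that("impurity importance flags leaked and informative features", {
  set.seed(2)
  n <- 150
  y <- rbinom(n, 1, 0.4)
  # label copied into a feature: must rank first
  leak <- feature_table(data.frame(leak = y, a = rnorm(n), b = rnorm(n)), y)
  expect_identical(feature_importance(leak, seed = 1)$feature[1], "leak")

  # an informative feature out-scores pure noise across seeds
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    y <- rbinom(n, 1, 0.4)
    x <- data.frame(info = y + rnorm(n, sd = 0.6),
                    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    fi <- feature_importance(feature_table(x, y), seed = s)
    fi$z[fi$feature == "info"] > max(fi$z[fi$feature != "info"])
  }, logical(1))
  expect_gte(sum(wins), 9L)

  # z-scores are normalized across features
  fi <- feature_importance(leak, seed = 1)
  expect_lt(abs(mean(fi$z)), 1e-9)
  expect_equal(stats::sd(fi$z), 1, tolerance = 1e-9)

  # constant features are tolerated, not errored
  cst <- feature_table(data.frame(c1 = rep(1, n), x = y + rnorm(n)), y)
  expect_silent(fi2 <- feature_importance(cst, seed = 1))
  expect_equal(fi2$importance[fi2$feature == "c1"], 0)
})

test_that("richer positional fingerprints are not worse than simple encoding", {
  # same underlying pairs featurized two ways; over seeds, the positional
  # fingerprint representation should carry at least as much signal
  lib <- monomer_library()
  res <- vapply(1:10, function(s) {
    ds <- make_sequence_labelled_set(400, seed = s)
    d2 <- build_dataset("D2", ds$labels, pairs = ds$pairs)
    d3 <- build_dataset("D3", ds$labels, pairs = ds$pairs, library = lib)
    c(evaluate_model(d2, "gradient_boosted_trees", seed = s)$auprc,
      evaluate_model(d3, "gradient_boosted_trees", seed = s)$auprc)
  }, numeric(2))
  expect_gte(mean(res[2, ]), mean(res[1, ]) - 0.05)
})
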