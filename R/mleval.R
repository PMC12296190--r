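#' Stratified train/evaluation splits
#'
#' Produces class-stratified splits of a labelled table: a 90/10 or 95/5
#' holdout, or stratified k-fold. Class proportions are preserved to within
#' one example per fold, and splits are deterministic for a fixed seed.
#'
#' @param labels Integer 0/1 vector.
#' @param scheme `"holdout_90_10"`, `"holdout_95_5"`, or `"skf"`.
#' @param k Number of folds for `"skf"` (default 10).
#' @param seed RNG seed.
#' @return For holdout schemes, a list with integer index vectors `train`
#'   and `eval`. For `"skf"`, a list of `k` such lists (each row appears in
#'   exactly one eval fold).
#' @export
split_indices <- function(labels,
                          scheme = c("holdout_90_10", "holdout_95_5", "skf"),
                          k = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("stratification requires both classes present")
  }
  if (any(table(labels) < 2L)) stop("need at least 2 examples per class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  idx_by_class <- split(seq_along(labels), labels)
  if (scheme == "skf") {
    fold_of <- integer(length(labels))
    for (cls in idx_by_class) {
      sh <- sample(cls)
      fold_of[sh] <- rep_len(seq_len(k), length(sh))
    }
    return(lapply(seq_len(k), function(f) {
      list(train = which(fold_of != f), eval = which(fold_of == f))
    }))
  }
  frac <- if (scheme == "holdout_90_10") 0.1 else 0.05
  eval_idx <- unlist(lapply(idx_by_class, function(cls) {
    n_eval <- max(1L, round(frac * length(cls)))
    sample(cls, n_eval)
  }), use.names = FALSE)
  eval_idx <- sort(eval_idx)
  list(train = setdiff(seq_along(labels), eval_idx), eval = eval_idx)
}

#' Area under the precision-recall curve (average-precision estimator)
#'
#' Step-wise estimator: scores are sorted decreasing, precision and recall
#' are evaluated at each distinct score threshold, and AUPRC is the sum of
#' precision times the recall increment. Preferred over ROC AUC under class
#' imbalance; a score vector independent of the labels gives an expected
#' AUPRC close to the positive prevalence.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Integer 0/1 vector.
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  pos <- sum(labels)
  if (pos == 0L) stop("no positive examples")
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]
  s <- scores[o]
  tp <- cumsum(l)
  n <- length(l)
  # last index within each run of tied scores
  step <- c(which(diff(s) != 0), n)
  precision <- tp[step] / step
  recall <- tp[step] / pos
  sum(diff(c(0, recall)) * precision)
}

#' Precision-recall curve points
#'
#' @inheritParams auprc
#' @return data.frame with columns `threshold`, `precision`, `recall`, one
#'   row per distinct score value.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- sum(labels)
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]
  s <- scores[o]
  tp <- cumsum(l)
  n <- length(l)
  step <- c(which(diff(s) != 0), n)
  data.frame(threshold = s[step], precision = tp[step] / step,
             recall = tp[step] / pos)
}

#' Confusion-matrix derived metrics
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return Named list with the counts plus `precision`, `recall`,
#'   `specificity`, `accuracy`, `f1` and `tp_fp_ratio`. Ratios with a zero
#'   denominator are `NA` (e.g. `tp_fp_ratio` when `fp == 0`).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  specificity <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  accuracy <- (tp + tn) / (tp + fp + tn + fn)
  f1 <- if (is.na(precision) || is.na(recall)) {
    NA_real_
  } else if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn, precision = precision,
       recall = recall, specificity = specificity, accuracy = accuracy,
       f1 = f1, tp_fp_ratio = if (fp == 0) NA_real_ else tp / fp)
}

.fit_and_score <- function(model, x_train, y_train, x_eval, seed) {
  switch(
    model,
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x_train),
                                     label = y_train, nthread = 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 6L,
                      eta = 0.3, nthread = 1L),
        data = dtrain, nrounds = 50L, verbose = 0)
      as.numeric(stats::predict(
        fit, xgboost::xgb.DMatrix(as.matrix(x_eval), nthread = 1L)))
    },
    random_forest = {
      fit <- randomForest::randomForest(
        x = x_train, y = factor(y_train, levels = c(0L, 1L)), ntree = 100L)
      as.numeric(stats::predict(fit, x_eval, type = "prob")[, "1"])
    },
    knn = {
      kk <- min(15L, nrow(x_train) - 1L)
      pred <- class::knn(train = as.matrix(x_train), test = as.matrix(x_eval),
                         cl = factor(y_train, levels = c(0L, 1L)), k = kk,
                         prob = TRUE)
      p_win <- attr(pred, "prob")
      ifelse(pred == "1", p_win, 1 - p_win)
    },
    stop("unknown model: ", model)
  )
}

#' Train a learner and evaluate it under class imbalance
#'
#' Fits one of three fixed-hyperparameter learners (gradient-boosted trees,
#' k-nearest neighbors, random forest) on a stratified training split and
#' reports confusion counts at a 0.5 score threshold, the derived rates,
#' and AUPRC on the held-out evaluation split.
#'
#' @param table A [feature_table()].
#' @param model `"gradient_boosted_trees"`, `"knn"`, or `"random_forest"`.
#' @param scheme Split scheme passed to [split_indices()] (holdout schemes
#'   only).
#' @param seed RNG seed for the split and the learner.
#' @param threshold Score threshold for the confusion counts (default 0.5).
#' @return An `eval_report`: list with `model`, `scheme`, `seed`, `n_train`,
#'   `n_eval`, the [confusion_metrics()] fields, `auprc`, and the eval
#'   `scores`.
#' @export
evaluate_model <- function(table,
                           model = c("gradient_boosted_trees", "knn",
                                     "random_forest"),
                           scheme = "holdout_90_10", seed = 1L,
                           threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  model <- match.arg(model)
  sp <- split_indices(table$labels, scheme = scheme, seed = seed)
  x <- table$features
  y <- table$labels
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scores <- .fit_and_score(model, x[sp$train, , drop = FALSE], y[sp$train],
                           x[sp$eval, , drop = FALSE], seed)
  y_eval <- y[sp$eval]
  pred <- as.integer(scores > threshold)
  m <- confusion_metrics(tp = sum(pred == 1L & y_eval == 1L),
                         fp = sum(pred == 1L & y_eval == 0L),
                         tn = sum(pred == 0L & y_eval == 0L),
                         fn = sum(pred == 0L & y_eval == 1L))
  structure(c(list(model = model, scheme = scheme, seed = seed,
                   n_train = length(sp$train), n_eval = length(sp$eval)),
              m, list(auprc = auprc(scores, y_eval), scores = scores,
                      labels_eval = y_eval)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$model, "|", x$scheme, "| seed", x$seed, "\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  precision %.3f  recall %.3f  accuracy %.3f  AUPRC %.3f\n",
              x$precision, x$recall, x$accuracy, x$auprc))
  invisible(x)
}

#' Impurity-based feature importance from a random forest
#'
#' Fits a random-forest classifier (default 75 trees) and reports the mean
#' decrease in impurity per feature, z-score normalized across features and
#' ranked descending. Constant features receive importance 0.
#'
#' @param table A [feature_table()].
#' @param n_trees Number of trees (default 75).
#' @param seed RNG seed.
#' @param top Optionally return only the `top` highest-ranked features.
#' @return data.frame with columns `feature`, `importance`, `z`, `rank`,
#'   sorted by decreasing importance.
#' @export
feature_importance <- function(table, n_trees = 75L, seed = 1L, top = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (length(unique(table$labels)) < 2L) stop("need both classes present")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = table$features, y = factor(table$labels, levels = c(0L, 1L)),
    ntree = as.integer(n_trees))
  imp <- fit$importance[, "MeanDecreaseGini"]
  z <- as.numeric(scale(imp))
  if (all(is.na(z))) z <- rep(0, length(imp))  # all-equal importances
  out <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    z = z, row.names = NULL)
  out <- out[order(-out$importance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), ]
  out
}
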