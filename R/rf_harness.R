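#' Cross-validation and forest configuration
#'
#' The fixed model specification used throughout: a 50-tree Gini forest with
#' all features eligible at every split, splits accepted only at a weighted
#' impurity decrease of at least 0.01, evaluated under 50 independently
#' shuffled stratified five-fold cross-validation partitions, all seeded from
#' one master seed (42 by default).
#'
#' @param n_shuffles number of shuffled CV repeats (default 50).
#' @param n_folds folds per repeat (default 5).
#' @param n_trees trees per forest (default 50).
#' @param min_impurity_decrease minimum weighted impurity decrease to accept
#'   a split (default 0.01).
#' @param seed master seed (default 42).
#' @param bootstrap bootstrap-sample each tree (default TRUE).
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(n_shuffles = 50, n_folds = 5, n_trees = 50,
                      min_impurity_decrease = 0.01, seed = 42,
                      bootstrap = TRUE) {
  if (n_folds < 2) stopf("n_folds must be >= 2")
  if (n_trees < 1) stopf("n_trees must be >= 1")
  if (min_impurity_decrease < 0) stopf("min_impurity_decrease must be >= 0")
  structure(list(n_shuffles = as.integer(n_shuffles),
                 n_folds = as.integer(n_folds),
                 n_trees = as.integer(n_trees),
                 min_impurity_decrease = min_impurity_decrease,
                 seed = as.integer(seed), bootstrap = isTRUE(bootstrap)),
            class = "cv_config")
}

#' Fit the forest and score new samples
#'
#' Thin wrapper around the compiled forest: returns per-sample class-1
#' probabilities (mean over trees of the leaf class fraction) and normalized
#' MDI feature importances.
#'
#' @param X_train,y_train training matrix and 0/1 labels.
#' @param X_test matrix of samples to score.
#' @param config a [cv_config()] (its `n_trees`, `min_impurity_decrease`,
#'   `bootstrap` fields are used).
#' @param seed forest seed.
#' @return list with `prob` (length `nrow(X_test)`) and `importance`
#'   (length `ncol(X_train)`, sums to 1 when any split occurred).
#' @export
rf_fit_predict <- function(X_train, y_train, X_test, config = cv_config(),
                           seed = config$seed) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  storage.mode(X_train) <- "double"
  storage.mode(X_test) <- "double"
  res <- .rf_fit_predict(X_train, as.integer(y_train), X_test,
                         config$n_trees, config$min_impurity_decrease,
                         as.integer(seed), config$bootstrap)
  names(res$importance) <- colnames(X_train)
  res
}

# stratified fold assignment; re-drawn (with a message) in the unlikely event
# a fold misses a class entirely
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  for (attempt in 1:100) {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(y[fold != f])) == 2 && sum(fold == f) > 0, logical(1)))
    if (ok) return(fold)
    message("re-drawing fold split: a class was absent from a training fold")
  }
  stopf("could not draw a valid stratified split (classes too small?)")
}

#' Repeated stratified cross-validation of the forest
#'
#' For each shuffle an independently shuffled stratified k-fold partition is
#' drawn; one forest is trained per fold and every sample is scored exactly
#' once out-of-fold. Per-shuffle metrics are computed on the pooled
#' out-of-fold scores; the reported performance is their mean over shuffles.
#'
#' @param X feature matrix (samples x features) or a named list of
#'   [feature_block()]s, which are column-bound over their common sample set
#'   (an error if the blocks disagree on samples).
#' @param y 0/1 labels (1 = responder, the ROC-positive class), named by
#'   sample id when `X` is a block list.
#' @param config a [cv_config()].
#' @param label data-combination label attached to the result.
#' @param features optional character vector restricting `X` to a feature
#'   subset (the "selected" features recorded on each run).
#' @return object of class `modelrun_set`: list with per-shuffle `runs`
#'   (scores, auc, metrics, importance, selected features) and a `summary`
#'   row of metric means.
#' @export
run_cv <- function(X, y, config = cv_config(), label = "model",
                   features = NULL) {
  if (is.list(X) && !is.matrix(X)) X <- bind_blocks(X, names(y))
  X <- as.matrix(X)
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(X))
    if (length(missing) > 0)
      stopf("unknown feature(s): %s", paste(missing, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  if (length(y) != nrow(X)) stopf("labels do not match sample rows")
  if (length(unique(y)) < 2) stopf("both classes must be present")

  runs <- vector("list", config$n_shuffles)
  for (s in seq_len(config$n_shuffles)) {
    fold <- stratified_folds(y, config$n_folds,
                             derive_seed(config$seed, 7, s))
    scores <- numeric(length(y))
    imp <- matrix(0, config$n_folds, ncol(X))
    for (f in seq_len(config$n_folds)) {
      tr <- fold != f
      fit <- rf_fit_predict(X[tr, , drop = FALSE], y[tr],
                            X[!tr, , drop = FALSE], config,
                            seed = derive_seed(config$seed, 7, s, f))
      scores[!tr] <- fit$prob
      imp[f, ] <- fit$importance
    }
    met <- classification_metrics(scores, y)
    runs[[s]] <- list(shuffle = s,
                      scores = stats::setNames(scores, rownames(X)),
                      auc = roc_auc(scores, y),
                      metrics = met,
                      importance = stats::setNames(colMeans(imp), colnames(X)),
                      features = colnames(X))
  }
  summary <- data.frame(
    label = label,
    n = length(y),
    roc_auc = mean(vapply(runs, `[[`, numeric(1), "auc")),
    sensitivity = mean(vapply(runs, function(r) r$metrics["sensitivity"], numeric(1))),
    specificity = mean(vapply(runs, function(r) r$metrics["specificity"], numeric(1))),
    mcc = mean(vapply(runs, function(r) r$metrics["mcc"], numeric(1))),
    stringsAsFactors = FALSE)
  structure(list(label = label, runs = runs, summary = summary,
                 y = stats::setNames(y, rownames(X)), config = config),
            class = "modelrun_set")
}

#' @export
print.modelrun_set <- function(x, ...) {
  cat(sprintf("<modelrun_set '%s': %d shuffles, mean ROC-AUC %.3f>\n",
              x$label, length(x$runs), x$summary$roc_auc))
  invisible(x)
}

#' Column-bind feature blocks over a common sample set
#'
#' @param blocks named list of [feature_block()]s.
#' @param samples optional sample ids to align on; defaults to the
#'   intersection of all blocks' samples. An error if any requested sample
#'   is absent from a block.
#' @return numeric matrix with feature columns from all blocks.
#' @export
bind_blocks <- function(blocks, samples = NULL) {
  common <- Reduce(intersect, lapply(blocks, block_samples))
  if (is.null(samples)) samples <- common
  bad <- setdiff(samples, common)
  if (length(bad) > 0)
    stopf("sample(s) missing from some block: %s",
          paste(head(bad, 5), collapse = ", "))
  do.call(cbind, lapply(blocks, function(b)
    b$values[samples, , drop = FALSE]))
}

#' Area under the ROC curve (midrank / Mann-Whitney formulation)
#'
#' @param scores prediction scores (higher = more responder-like).
#' @param labels 0/1 labels; class 1 is the positive class.
#' @return AUC in \[0, 1\]; 0.5 when all scores tie.
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("roc_auc needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a score threshold
#'
#' Predicts class 1 when `score >= threshold` and reports sensitivity,
#' specificity, PPV, NPV and the Matthews correlation coefficient (0 by
#' convention when any confusion margin is zero).
#'
#' @param scores prediction scores.
#' @param labels 0/1 labels.
#' @param threshold classification threshold (default 0.5).
#' @return named numeric vector: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `mcc`, plus the confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, mcc = mcc,
    tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Feature importance report across trained models
#'
#' Aggregates one or more `modelrun_set`s sharing a data-combination label:
#' a feature's selection frequency is the fraction of trained models whose
#' selected set contains it, and its importance the mean relative Gini (MDI)
#' over the models containing it. Features selected in fewer than `min_freq`
#' of models are omitted. The `1/M` reference line uses M = the number of
#' features in the final model.
#'
#' @param runsets a `modelrun_set` or list of them (same label).
#' @param min_freq minimum selection frequency to report (default 0.15).
#' @return list with `table` (data.frame `feature`, `frequency`,
#'   `mean_importance`), `baseline` (1/M) and `n_models`.
#' @export
importance_report <- function(runsets, min_freq = 0.15) {
  if (inherits(runsets, "modelrun_set")) runsets <- list(runsets)
  if (length(runsets) == 0) stopf("empty run set")
  labels <- unique(vapply(runsets, `[[`, character(1), "label"))
  if (length(labels) > 1)
    stopf("importance_report expects runs sharing one label, got: %s",
          paste(labels, collapse = ", "))
  runs <- do.call(c, lapply(runsets, `[[`, "runs"))
  n_models <- length(runs)
  feats <- sort(unique(unlist(lapply(runs, `[[`, "features"))))
  freq <- vapply(feats, function(f)
    mean(vapply(runs, function(r) f %in% r$features, logical(1))), numeric(1))
  mimp <- vapply(feats, function(f) {
    v <- unlist(lapply(runs, function(r)
      if (f %in% r$features) r$importance[[f]] else NULL))
    mean(v)
  }, numeric(1))
  keep <- freq >= min_freq
  tab <- data.frame(feature = feats[keep], frequency = unname(freq[keep]),
                    mean_importance = unname(mimp[keep]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mean_importance), , drop = FALSE]
  m_final <- length(runs[[n_models]]$features)
  list(table = tab, baseline = 1 / m_final, n_models = n_models)
}
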