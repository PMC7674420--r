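#' Wrapper forward feature selection with scheduled pool pruning
#'
#' Greedy forward selection driven by cross-validated ROC-AUC. Per
#' iteration, every pool feature is scored by the CV AUC of the current set
#' plus that feature; the best is added if it strictly improves the AUC
#' (tolerance 1e-6). When several candidates tie, all of them are first
#' added together to see whether that performs better; if not, one tied
#' feature is chosen at random and the others remain in the pool. After each
#' accepted addition, the worst-scoring fraction of the pool is removed to
#' save computation: the fraction starts at `frac` (0.4: 40\% of a pool of
#' 100 is removed in iteration 1) and shrinks by `step` per iteration; once
#' below 0.1 the decrement becomes 0.01, and when the fraction rounds to
#' zero features exactly one is removed per iteration. Selection stops when
#' no addition improves the AUC or `max_features` is reached. Removal is
#' permanent (only tied candidates explicitly stay in the pool).
#'
#' The removal count applies to the pool size at the start of the
#' iteration's scan, and "worst performing" means lowest single-addition CV
#' AUC in that scan — the only per-feature score the procedure computes.
#'
#' @param X feature matrix (samples x features) containing pool and
#'   always-in columns.
#' @param y 0/1 labels.
#' @param pool candidate feature names.
#' @param always_in features fixed in every evaluation (e.g. the Diet
#'   one-hot triple); not counted against `max_features`.
#' @param config a [cv_config()] for the inner evaluations; defaults to a
#'   reduced 5-shuffle protocol for tractability (the final set should be
#'   re-evaluated under the full 50).
#' @param max_features maximum number of selected features (`Inf` for
#'   unlimited).
#' @param frac initial pool fraction removed per iteration.
#' @param step per-iteration decrement of `frac`.
#' @param seed seed for tie-breaking draws.
#' @param tol AUC improvement/tie tolerance.
#' @return object of class `selection_trace`: list with `selected` (in
#'   addition order), `always_in`, `auc` (of the final set), and `trace`
#'   (data.frame per iteration: `pool_size`, `added`, `n_removed`, `auc`).
#' @export
forward_select <- function(X, y, pool, always_in = character(0),
                           config = cv_config(n_shuffles = 5),
                           max_features = 8, frac = 0.4, step = 0.1,
                           seed = config$seed, tol = 1e-6) {
  if (max_features < 1) stopf("max_features must be >= 1")
  X <- as.matrix(X)
  missing <- setdiff(c(pool, always_in), colnames(X))
  if (length(missing) > 0)
    stopf("feature(s) absent from X: %s", paste(missing, collapse = ", "))

  cv_auc <- function(feats) {
    if (length(feats) == 0) return(0.5)
    run_cv(X, y, config, features = feats)$summary$roc_auc
  }

  current <- always_in
  best_auc <- cv_auc(current)
  trace <- list()
  iter <- 0

  while (length(pool) > 0 &&
         length(setdiff(current, always_in)) < max_features) {
    iter <- iter + 1
    pool_size <- length(pool)
    scan <- vapply(pool, function(f) cv_auc(c(current, f)), numeric(1))
    best_score <- max(scan)
    if (best_score <= best_auc + tol) break   # no addition improves: stop

    tied <- pool[scan >= best_score - tol]
    if (length(tied) > 1) {
      auc_all <- cv_auc(c(current, tied))
      if (auc_all > best_score + tol) {
        added <- tied
        new_auc <- auc_all
      } else {
        set.seed(derive_seed(seed, 11, iter))
        added <- sample(tied, 1)
        new_auc <- best_score
      }
    } else {
      added <- tied
      new_auc <- best_score
    }
    current <- c(current, added)
    pool <- setdiff(pool, added)
    best_auc <- new_auc

    # scheduled pruning of the candidate pool
    n_rm <- floor(frac * pool_size)
    if (n_rm == 0) n_rm <- 1
    remaining_scan <- scan[pool]       # scores of features still in the pool
    n_rm <- min(n_rm, length(pool))
    if (n_rm > 0) {
      worst <- names(sort(remaining_scan))[seq_len(n_rm)]
      pool <- setdiff(pool, worst)
    }
    frac <- max(frac - step, 0)
    if (frac < 0.1) step <- 0.01

    trace[[iter]] <- data.frame(pool_size = pool_size,
                                added = paste(added, collapse = ","),
                                n_removed = n_rm, auc = best_auc,
                                stringsAsFactors = FALSE)
  }

  structure(list(selected = setdiff(current, always_in),
                 always_in = always_in, auc = best_auc,
                 trace = do.call(rbind, trace)),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace: %d selected, AUC %.3f>\n",
              length(x$selected), x$auc))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive subset search over metabolite pairs / triplets
#'
#' Evaluates every subset of the requested sizes (always-in features
#' included in each model) by CV ROC-AUC and returns the best subset with
#' the full score table.
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param features candidate features to form subsets from.
#' @param sizes subset sizes (default pairs and triplets).
#' @param always_in features included in every evaluation.
#' @param config a [cv_config()].
#' @return list with `best` (character vector), `best_auc`, and `table`
#'   (data.frame `subset`, `size`, `auc`).
#' @export
exhaustive_subsets <- function(X, y, features, sizes = c(2, 3),
                               always_in = character(0),
                               config = cv_config(n_shuffles = 5)) {
  if (length(features) < max(sizes))
    stopf("need at least %d features for subsets of size %d",
          max(sizes), max(sizes))
  X <- as.matrix(X)
  rows <- list()
  for (sz in sizes) {
    subs <- combn(features, sz, simplify = FALSE)
    for (s in subs) {
      auc <- run_cv(X, y, config, features = c(always_in, s))$summary$roc_auc
      rows[[length(rows) + 1]] <- data.frame(
        subset = paste(s, collapse = ","), size = sz, auc = auc,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  best_row <- which.max(tab$auc)
  list(best = strsplit(tab$subset[best_row], ",")[[1]],
       best_auc = tab$auc[best_row], table = tab)
}
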