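#' Compare two AUC (or other) distributions
#'
#' Two-sample unpaired t-test when both samples pass a Shapiro-Wilk
#' Gaussianity check at alpha = 0.05, Mann-Whitney U otherwise; two-sided.
#' Identical constant samples are degenerate and return p = 1 by convention
#' (with a message). Significance is conventionally declared at p < 0.05.
#'
#' @param a,b numeric samples, each of size >= 3.
#' @param alpha Shapiro-Wilk gate level (default 0.05).
#' @return list with `p_value`, `test` ("t" or "mann_whitney"), `statistic`.
#' @export
compare_distributions <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3) stopf("both samples must have size >= 3")
  if (var(a) == 0 && var(b) == 0 && a[1] == b[1]) {
    message("identical constant samples: degenerate comparison, p = 1")
    return(list(p_value = 1, test = "degenerate", statistic = NA_real_))
  }
  normal <- function(x) {
    if (var(x) == 0) return(FALSE)
    shapiro.test(x)$p.value >= alpha
  }
  if (normal(a) && normal(b)) {
    tt <- t.test(a, b)
    list(p_value = tt$p.value, test = "t", statistic = unname(tt$statistic))
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    list(p_value = wt$p.value, test = "mann_whitney",
         statistic = unname(wt$statistic))
  }
}

#' Shuffle labels preserving class counts
#' @param y 0/1 label vector.
#' @param seed integer seed.
#' @return a permutation of `y`.
#' @export
permute_labels <- function(y, seed) {
  set.seed(seed)
  y[sample.int(length(y))]
}

#' Evaluate stored out-of-fold scores against an arbitrary label vector
#'
#' Computes the per-shuffle ROC-AUC of a fitted `modelrun_set`'s stored
#' out-of-fold scores against `labels` (ordered like the run's samples).
#' With the run's own labels this reproduces its true per-shuffle AUCs
#' exactly.
#'
#' @param runset a `modelrun_set` from [run_cv()].
#' @param labels 0/1 labels in the runset's sample order.
#' @return numeric vector of per-shuffle AUCs.
#' @export
evaluate_on_labels <- function(runset, labels) {
  vapply(runset$runs, function(r) roc_auc(r$scores, labels), numeric(1))
}

#' Label-permutation robustness test
#'
#' Shuffles class labels `n_perm` times (preserving class counts) and
#' collects a null AUC distribution under one of three setups:
#' \describe{
#'   \item{`retrain_fixed_features`}{retrain the forest on permuted labels
#'     using the features selected on the true labels (setup i);}
#'   \item{`retrain_with_reselection`}{rerun forward selection on the
#'     permuted labels before retraining, probing whether the wrapper can
#'     fit patterns in pure noise (setup ii);}
#'   \item{`evaluate_trained_on_shuffled`}{evaluate the stored true-label
#'     models' out-of-fold scores against the shuffled labels (setup iii).}
#' }
#' The null distribution (one mean AUC per permutation) is compared to the
#' true distribution (the reference run's per-shuffle AUCs) with
#' [compare_distributions()]; an empirical-quantile p-value is also
#' reported for reference.
#'
#' @param X feature matrix (needed for the retraining modes).
#' @param reference the true-label `modelrun_set` from [run_cv()].
#' @param mode one of the three setups above.
#' @param n_perm number of permutations (default 50).
#' @param config a [cv_config()] for retraining (defaults to the
#'   reference's config).
#' @param seed master seed; per-permutation seeds derive from it.
#' @param selection_args list of arguments for [forward_select()] in the
#'   reselection mode (`pool`, `always_in`, `max_features`, ...).
#' @return object of class `permutation_result`: `mode`, `true_auc`
#'   (per-shuffle), `null_auc` (per-permutation), `p_value`, `test`,
#'   `p_empirical`.
#' @export
permute_and_evaluate <- function(X, reference,
                                 mode = c("retrain_fixed_features",
                                          "retrain_with_reselection",
                                          "evaluate_trained_on_shuffled"),
                                 n_perm = 50, config = reference$config,
                                 seed = config$seed, selection_args = list()) {
  mode <- match.arg(mode)
  y <- unname(reference$y)
  true_auc <- vapply(reference$runs, `[[`, numeric(1), "auc")
  features <- reference$runs[[1]]$features
  if (mode == "retrain_fixed_features" && is.null(features))
    stopf("mode 'retrain_fixed_features' needs the reference's feature set")

  null_auc <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    yp <- permute_labels(y, derive_seed(seed, 13, k))
    null_auc[k] <- switch(
      mode,
      retrain_fixed_features = {
        cfg <- config
        cfg$seed <- derive_seed(seed, 14, k)
        run_cv(X, yp, cfg, features = features)$summary$roc_auc
      },
      retrain_with_reselection = {
        cfg <- selection_args$config %||% cv_config(n_shuffles = 3)
        cfg$seed <- derive_seed(seed, 14, k)
        tr <- forward_select(X, yp,
                             pool = selection_args$pool %||% colnames(X),
                             always_in = selection_args$always_in %||% character(0),
                             config = cfg,
                             max_features = selection_args$max_features %||% 8)
        feats <- c(tr$always_in, tr$selected)
        if (length(feats) == 0) 0.5
        else run_cv(X, yp, cfg, features = feats)$summary$roc_auc
      },
      evaluate_trained_on_shuffled = mean(evaluate_on_labels(reference, yp)))
  }
  cmp <- compare_distributions(true_auc, null_auc)
  structure(list(mode = mode, n_permutations = n_perm,
                 true_auc = true_auc, null_auc = null_auc,
                 p_value = cmp$p_value, test = cmp$test,
                 p_empirical = (1 + sum(null_auc >= mean(true_auc))) /
                   (n_perm + 1)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result '%s': true mean AUC %.3f, null mean %.3f, p = %.3g (%s)>\n",
              x$mode, mean(x$true_auc), mean(x$null_auc), x$p_value, x$test))
  invisible(x)
}
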