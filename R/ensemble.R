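#' Admit models into the ensemble pool
#'
#' Flattens one or more `modelrun_set`s into per-(data combination, shuffle)
#' candidate models and admits those whose ROC-AUC strictly exceeds the
#' threshold (a model at exactly the threshold is excluded). With 7 data
#' combinations under 50 shuffles the candidate pool is 350 models.
#'
#' @param runsets list of `modelrun_set`s (one per data combination).
#' @param auc_threshold admission threshold, strict ">" (default 0.62, the
#'   diet-only baseline).
#' @return object of class `model_pool`: list with `models` (admitted:
#'   label, shuffle, auc, per-sample out-of-fold scores), `n_candidates`,
#'   `n_admitted`, `threshold`.
#' @export
admit_models <- function(runsets, auc_threshold = 0.62) {
  if (inherits(runsets, "modelrun_set")) runsets <- list(runsets)
  models <- list()
  for (rs in runsets) {
    for (r in rs$runs) {
      models[[length(models) + 1]] <-
        list(label = rs$label, shuffle = r$shuffle, auc = r$auc,
             scores = r$scores)
    }
  }
  n_cand <- length(models)
  admitted <- Filter(function(m) m$auc > auc_threshold, models)
  if (length(admitted) == 0)
    stopf("no model exceeds ROC-AUC %.3f; lower the admission threshold",
          auc_threshold)
  structure(list(models = admitted, n_candidates = n_cand,
                 n_admitted = length(admitted), threshold = auc_threshold),
            class = "model_pool")
}

#' @export
print.model_pool <- function(x, ...) {
  cat(sprintf("<model_pool: %d of %d models admitted at AUC > %.2f>\n",
              x$n_admitted, x$n_candidates, x$threshold))
  invisible(x)
}

#' Aggregate one individual's prediction scores across models
#'
#' Four scoring schemes over the per-model scores available for an
#' individual:
#' \describe{
#'   \item{mean}{arithmetic mean of all scores;}
#'   \item{majority}{scores rounded to 0/1 (s >= 0.5 rounds up); the
#'     majority class is returned as a 0/1 score, 0.5 on a tie;}
#'   \item{confident_mean}{mean of the scores at or beyond the confidence
#'     band bounds (s <= lower or s >= upper); excluded if none qualify;}
#'   \item{confident_majority}{rounding + majority over confident scores
#'     only; excluded if none qualify.}
#' }
#'
#' @param scores numeric vector of per-model prediction scores for one
#'   individual (length >= 1; an empty vector yields exclusion).
#' @param method scoring scheme.
#' @param band length-2 confidence band `(lower, upper)`, 0 < lower <
#'   upper < 1; scores strictly inside the band are uninformative for the
#'   confident schemes.
#' @return list with `s` (aggregated score, `NA` when excluded),
#'   `n_models` (contributing count) and `excluded`.
#' @export
ensemble_score <- function(scores,
                           method = c("mean", "majority", "confident_mean",
                                      "confident_majority"),
                           band = c(0.25, 0.75)) {
  method <- match.arg(method)
  if (band[1] <= 0 || band[2] >= 1 || band[1] >= band[2])
    stopf("band must satisfy 0 < lower < upper < 1")
  if (length(scores) == 0)
    return(list(s = NA_real_, n_models = 0L, excluded = TRUE))
  majority <- function(v) {
    f1 <- mean(v >= 0.5)
    if (f1 > 0.5) 1 else if (f1 < 0.5) 0 else 0.5
  }
  if (method %in% c("confident_mean", "confident_majority")) {
    conf <- scores <= band[1] | scores >= band[2]
    if (!any(conf))
      return(list(s = NA_real_, n_models = 0L, excluded = TRUE))
    scores <- scores[conf]
  }
  s <- switch(method,
              mean = mean(scores),
              confident_mean = mean(scores),
              majority = majority(scores),
              confident_majority = majority(scores))
  list(s = s, n_models = length(scores), excluded = FALSE)
}

#' Ensemble scores for every individual covered by a model pool
#'
#' Individuals receive scores only from models (shuffles) in which they were
#' scored out-of-fold; models lacking an individual's data contribute
#' nothing.
#'
#' @param pool a `model_pool` from [admit_models()].
#' @param method,band see [ensemble_score()].
#' @return data.frame `sample_id`, `s`, `n_models`, `excluded`.
#' @export
ensemble_scores <- function(pool, method = "mean", band = c(0.25, 0.75)) {
  ids <- sort(unique(unlist(lapply(pool$models, function(m) names(m$scores)))))
  rows <- lapply(ids, function(id) {
    sc <- unlist(lapply(pool$models, function(m) m$scores[id]))
    sc <- sc[!is.na(sc)]
    es <- ensemble_score(sc, method, band)
    data.frame(sample_id = id, s = es$s, n_models = es$n_models,
               excluded = es$excluded, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Clinical-metric sweep over classification thresholds
#'
#' At each threshold, individuals with ensemble score >= threshold are
#' predicted responders; sensitivity, specificity, PPV, NPV and MCC are
#' computed on non-excluded individuals only. Coverage (the number of
#' non-excluded individuals) is always reported alongside.
#'
#' @param scores data.frame from [ensemble_scores()].
#' @param labels named 0/1 vector (names = sample ids).
#' @param grid ascending threshold grid; the default 0 to 1 in steps of
#'   0.05 includes the 0.30 and 0.70 operating points.
#' @return data.frame: `threshold`, `sensitivity`, `ppv`, `specificity`,
#'   `npv`, `mcc`, `n_covered`.
#' @export
sweep_thresholds <- function(scores, labels, grid = seq(0, 1, by = 0.05)) {
  keep <- !scores$excluded
  if (!any(keep)) stopf("all individuals are excluded by the scoring scheme")
  s <- scores$s[keep]
  y <- labels[scores$sample_id[keep]]
  if (anyNA(y)) stopf("labels missing for some scored individuals")
  rows <- lapply(grid, function(th) {
    m <- classification_metrics(s, y, threshold = th)
    data.frame(threshold = th, sensitivity = m[["sensitivity"]],
               ppv = m[["ppv"]], specificity = m[["specificity"]],
               npv = m[["npv"]], mcc = m[["mcc"]], n_covered = length(y))
  })
  do.call(rbind, rows)
}
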