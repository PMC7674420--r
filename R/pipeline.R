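#' Default data-combination definitions
#'
#' Seven block combinations mirroring the kinds of model inputs reported in
#' the study's ensemble (diet alone, diet plus clinical, genetic risk
#' scores, postprandial volatility, butyrate producers, and microbiome +
#' metabolome integrations). Combination labels concatenate block labels
#' with `"."`.
#'
#' @return named list: each element a character vector of block labels.
#' @export
default_combinations <- function() {
  combos <- list(c("Diet"),
                 c("Diet", "Clinical"),
                 c("Diet", "GRS"),
                 c("Diet", "PostPran"),
                 c("Diet", "MGm_B1"),
                 c("Diet", "16S_B", "LC-MS"),
                 c("Diet", "MGm_B1", "LC-MS"))
  names(combos) <- vapply(combos, paste, character(1), collapse = ".")
  combos
}

#' Pipeline configuration
#'
#' One structured configuration drives the whole run: the synthetic-cohort
#' generator (or paths to real feature tables), the data combinations, the
#' CV protocol, optional forward selection per combination, permutation
#' settings and the ensemble. All randomness derives from `seed`.
#'
#' @param synth a [synth_config()] describing the simulated cohort.
#' @param combinations named list of block-label vectors (see
#'   [default_combinations()]).
#' @param cv a [cv_config()].
#' @param select named list: for each combination label to forward-select,
#'   a list with `pool_blocks` (blocks whose features form the candidate
#'   pool; remaining blocks are always-in) and optional `max_features`,
#'   `n_shuffles`.
#' @param ensemble list: `auc_threshold`, `method`, `band`, `grid`.
#' @param permutation list: `mode`, `n_perm`, or `NULL` to skip.
#' @param seed master seed; overrides the seeds in `synth` and `cv`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            combinations = default_combinations(),
                            cv = cv_config(),
                            select = list(),
                            ensemble = list(auc_threshold = 0.62,
                                            method = "confident_mean",
                                            band = c(0.25, 0.75),
                                            grid = seq(0, 1, by = 0.05)),
                            permutation = NULL,
                            seed = 42) {
  structure(list(synth = synth, combinations = combinations, cv = cv,
                 select = select, ensemble = ensemble,
                 permutation = permutation, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto the [pipeline_config()],
#' [synth_config()] and [cv_config()] arguments; unspecified fields keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  synth <- do.call(synth_config, raw$synth %||% list())
  cv <- do.call(cv_config, raw$cv %||% list())
  combos <- raw$combinations %||% default_combinations()
  ens <- utils::modifyList(list(auc_threshold = 0.62, method = "confident_mean",
                                band = c(0.25, 0.75), grid = seq(0, 1, 0.05)),
                           raw$ensemble %||% list())
  pipeline_config(synth = synth, combinations = combos, cv = cv,
                  select = raw$select %||% list(), ensemble = ens,
                  permutation = raw$permutation,
                  seed = raw$seed %||% 42)
}

# five GRS definitions over random disjoint SNP subsets with N(0, 0.15)
# weights: stand-ins for literature-curated score definitions
default_grs_definitions <- function(snp_ids, seed, n_scores = 5,
                                    snps_per_score = 6) {
  set.seed(derive_seed(seed, 505))
  n_need <- n_scores * snps_per_score
  chosen <- sample(snp_ids, min(n_need, length(snp_ids)))
  split_ix <- rep_len(seq_len(n_scores), length(chosen))
  lapply(seq_len(n_scores), function(k) {
    ids <- chosen[split_ix == k]
    data.frame(snp_id = ids, effect_size = rnorm(length(ids), 0, 0.15),
               stringsAsFactors = FALSE)
  })
}

# featurize: derived blocks (GRS from genotype dosages, PostPran from series)
build_derived_blocks <- function(blocks, pp, seed) {
  if ("Genotype" %in% names(blocks)) {
    dos <- blocks$Genotype$values
    defs <- default_grs_definitions(colnames(dos), seed)
    g <- vapply(defs, function(d) grs(dos, d), numeric(nrow(dos)))
    colnames(g) <- sprintf("grs_%d", seq_along(defs))
    rownames(g) <- rownames(dos)
    blocks$GRS <- feature_block(g, "GRS")
  }
  if (!is.null(pp)) blocks$PostPran <- postprandial_feature_block(pp)
  blocks
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> label -> featurize -> train/select -> (optional)
#' permute -> ensemble -> report on a synthetic cohort, writing every
#' artifact (TSV tables, JSON model runs, a manifest of seeds and versions)
#' into `out_dir`. Reruns with the same configuration are byte-identical.
#' Ground-truth responder labels from the generator are written for
#' validation but never read by any analysis stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the run's in-memory artifacts: `cohort`,
#'   `labels`, `blocks`, `runsets`, `pool`, `ensemble_table`, `sweep`,
#'   `metrics` (the per-combination metric table).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  synth <- config$synth
  synth$seed <- config$seed
  cv <- config$cv
  cv$seed <- derive_seed(config$seed, 2)

  say("[simulate] cohort of ", synth$n_participants, " participants")
  sim <- simulate_cohort(synth)
  blocks <- simulate_omics_blocks(synth, sim$cohort)
  pp <- simulate_postprandial(synth, sim$cohort, sim$truth)
  write_cohort_tsv(sim$cohort, file.path(out_dir, "cohort.tsv"))
  write.table(sim$truth, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_postprandial_tsv(pp, file.path(out_dir, "postprandial.tsv"))

  say("[label] responder / non-responder outcomes")
  labels <- responder_labels(sim$cohort)
  write_labels_tsv(labels, file.path(out_dir, "labels.tsv"))
  usable <- labels[labels$class != "excluded", ]
  y_all <- stats::setNames(usable$y, usable$sample_id)

  say("[featurize] derived blocks + block-wise missingness")
  blocks <- build_derived_blocks(blocks, pp, config$seed)
  miss <- inject_missingness(blocks, synth)
  blocks <- miss$blocks
  for (lab in names(blocks))
    write_feature_block_tsv(blocks[[lab]],
                            file.path(out_dir, paste0("block_", gsub("[^A-Za-z0-9_]", "_", lab), ".tsv")))

  # validate combinations before any compute
  for (combo in config$combinations) {
    undefined <- setdiff(combo, names(blocks))
    if (length(undefined) > 0)
      stopf("combination references undefined block(s): %s",
            paste(undefined, collapse = ", "))
  }

  runsets <- list()
  for (lab in names(config$combinations)) {
    combo <- config$combinations[[lab]]
    ids <- Reduce(intersect, lapply(blocks[combo], block_samples))
    ids <- intersect(ids, names(y_all))
    X <- bind_blocks(blocks[combo], ids)
    y <- y_all[ids]
    sel <- config$select[[lab]]
    feats <- NULL
    if (!is.null(sel)) {
      say("[select] forward selection for ", lab)
      pool_feats <- unlist(lapply(blocks[sel$pool_blocks],
                                  function(b) colnames(b$values)))
      always <- setdiff(colnames(X), pool_feats)
      sel_cv <- cv_config(n_shuffles = sel$n_shuffles %||% 5,
                          seed = derive_seed(config$seed, 3))
      tr <- forward_select(X, y, pool = pool_feats, always_in = always,
                           config = sel_cv,
                           max_features = sel$max_features %||% 8)
      feats <- c(tr$always_in, tr$selected)
      jsonlite::write_json(unclass(tr),
                           file.path(out_dir, paste0("selection_", gsub("[^A-Za-z0-9_]", "_", lab), ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    say("[train] ", lab, " (n = ", length(y), ")")
    runsets[[lab]] <- run_cv(X, y, cv, label = lab, features = feats)
  }

  metrics <- do.call(rbind, lapply(runsets, `[[`, "summary"))
  rownames(metrics) <- NULL
  write.table(format(metrics, digits = 6), file.path(out_dir, "metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  perm_results <- NULL
  if (!is.null(config$permutation)) {
    say("[permute] robustness checks")
    pm <- config$permutation
    target <- pm$combination %||% names(runsets)[length(runsets)]
    ids <- names(runsets[[target]]$y)
    X <- bind_blocks(blocks[config$combinations[[target]]], ids)
    perm_results <- permute_and_evaluate(
      X, runsets[[target]], mode = pm$mode %||% "retrain_fixed_features",
      n_perm = pm$n_perm %||% 50, seed = derive_seed(config$seed, 4))
    jsonlite::write_json(unclass(perm_results),
                         file.path(out_dir, "permutation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  say("[ensemble] confidence-gated aggregation")
  ens <- config$ensemble
  pool <- admit_models(runsets, ens$auc_threshold)
  etab <- ensemble_scores(pool, ens$method, ens$band)
  sweep <- sweep_thresholds(etab, y_all, ens$grid)
  write.table(format(etab, digits = 6),
              file.path(out_dir, "ensemble_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(format(sweep, digits = 6),
              file.path(out_dir, "ensemble_sweep.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("responderRF")),
                   n_combinations = length(config$combinations),
                   n_candidate_models = pool$n_candidates,
                   n_admitted_models = pool$n_admitted,
                   complete_cases = length(miss$complete_cases))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  # per-combination model runs (scores, features, importances, metrics)
  runs_json <- lapply(runsets, function(rs)
    list(label = rs$label, summary = rs$summary,
         runs = lapply(rs$runs, function(r)
           list(shuffle = r$shuffle, auc = r$auc,
                metrics = as.list(r$metrics),
                features = r$features,
                importance = as.list(r$importance),
                scores = as.list(r$scores)))))
  jsonlite::write_json(runs_json, file.path(out_dir, "model_runs.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = sim$cohort, labels = labels, blocks = blocks,
                 runsets = runsets, pool = pool, ensemble_table = etab,
                 sweep = sweep, metrics = metrics,
                 permutation = perm_results,
                 complete_cases = miss$complete_cases))
}

#' Summarize a completed pipeline run directory
#'
#' Reads the serialized artifacts and prints the per-combination metric
#' table (means over shuffles), the feature-importance report under the
#' 15\% selection-frequency rule, and the ensemble threshold sweep.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param min_freq importance selection-frequency floor (default 0.15).
#' @return invisibly, a list with `metrics`, `importance`, `sweep`.
#' @export
report_run <- function(run_dir, min_freq = 0.15) {
  metrics_path <- file.path(run_dir, "metrics.tsv")
  if (!file.exists(metrics_path))
    stopf("incomplete run: %s is missing", metrics_path)
  metrics <- read.delim(metrics_path)
  cat("== Model performance (means over CV shuffles) ==\n")
  print(metrics, row.names = FALSE)

  runs <- jsonlite::read_json(file.path(run_dir, "model_runs.json"))
  importance <- lapply(runs, function(rs) {
    feats <- sort(unique(unlist(lapply(rs$runs, function(r) unlist(r$features)))))
    freq <- vapply(feats, function(f)
      mean(vapply(rs$runs, function(r) f %in% unlist(r$features), logical(1))),
      numeric(1))
    imp <- vapply(feats, function(f) {
      v <- unlist(lapply(rs$runs, function(r) r$importance[[f]]))
      if (is.null(v)) NA_real_ else mean(v)
    }, numeric(1))
    keep <- freq >= min_freq
    data.frame(feature = feats[keep], frequency = unname(freq[keep]),
               mean_importance = unname(imp[keep]))
  })
  cat(sprintf("\n== Feature importance (selection frequency >= %d%%) ==\n",
              round(100 * min_freq)))
  for (lab in names(importance)) {
    tab <- importance[[lab]]
    tab <- tab[order(-tab$mean_importance), ]
    cat("--", lab, "--\n")
    print(head(tab, 10), row.names = FALSE)
  }

  sweep_path <- file.path(run_dir, "ensemble_sweep.tsv")
  sweep <- NULL
  if (file.exists(sweep_path)) {
    sweep <- read.delim(sweep_path)
    cat("\n== Ensemble threshold sweep ==\n")
    print(sweep, row.names = FALSE)
  } else {
    warning("incomplete run: ensemble sweep missing; partial report")
  }
  invisible(list(metrics = metrics, importance = importance, sweep = sweep))
}
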