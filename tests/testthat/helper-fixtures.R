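# Reduced-scale generator config: full structure, small blocks, fast tests.
small_synth_config <- function(seed = 42, ...) {
  synth_config(n_participants = 60,
               block_sizes = c(Clinical = 6, `16S_B` = 40, MGm_B1 = 11,
                               `LC-MS` = 25, Genotype = 80),
               seed = seed, ...)
}

# labelled (X, y) with optional planted signal in feature 1
sim_xy <- function(n = 200, p = 5, effect = 0, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + effect * y
  rownames(X) <- sprintf("s%03d", seq_len(n))
  colnames(X) <- sprintf("f%02d", seq_len(p))
  list(X = X, y = stats::setNames(y, rownames(X)))
}

fast_cv <- function(n_shuffles = 5, seed = 42, ...)
  cv_config(n_shuffles = n_shuffles, seed = seed, ...)
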