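test_that("config invariants are enforced", {
  expect_error(cv_config(n_folds = 1), "n_folds")
  expect_error(cv_config(n_trees = 0), "n_trees")
  expect_error(cv_config(min_impurity_decrease = -1), "min_impurity")
})

test_that("roc_auc handles the canonical cases and matches the pairwise oracle", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), y), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), y), 0)
  expect_equal(roc_auc(rep(0.5, 4), y), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(10)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    yy <- c(0, 1, rbinom(n - 2, 1, 0.5))
    ss <- round(runif(n), 2)  # coarse scores force ties
    expect_equal(roc_auc(ss, yy), oracle_auc(ss, yy), tolerance = 1e-12)
  }
})

test_that("classification_metrics reproduces hand-computed confusion results", {
  # 40 TP, 45 TN, 5 FP, 10 FN
  labels <- c(rep(1, 50), rep(0, 50))
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 5), rep(0.1, 45))
  m <- classification_metrics(scores, labels)
  expect_equal(unname(m["sensitivity"]), 0.8)
  expect_equal(unname(m["specificity"]), 0.9)
  expect_equal(unname(m["mcc"]), 0.703, tolerance = 1e-3)
  perfect <- classification_metrics(labels, labels)
  expect_equal(unname(perfect[c("sensitivity", "specificity", "mcc")]),
               c(1, 1, 1))
  low <- classification_metrics(rep(0.1, 100), labels)
  expect_equal(unname(low["sensitivity"]), 0)
  expect_equal(unname(low["specificity"]), 1)
  expect_equal(unname(low["mcc"]), 0)  # zero-margin convention
})

test_that("run_cv is deterministic and scores every sample once per shuffle", {
  d <- sim_xy(n = 80, p = 3, effect = 1, seed = 2)
  a <- run_cv(d$X, d$y, fast_cv(3), label = "m")
  b <- run_cv(d$X, d$y, fast_cv(3), label = "m")
  expect_identical(a$runs, b$runs)
  for (r in a$runs) {
    expect_length(r$scores, 80)
    expect_true(all(r$scores >= 0 & r$scores <= 1))
    expect_equal(sum(r$importance), 1, tolerance = 1e-9)
  }
  expect_equal(names(a$runs[[1]]$scores), rownames(d$X))
})

test_that("a perfectly separating feature drives AUC to ~1, pure noise to ~0.5", {
  set.seed(3)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sep = y + runif(n, -0.3, 0.3),
             noise = rnorm(n))
  rownames(X) <- paste0("s", 1:n)
  rs <- run_cv(X, stats::setNames(y, rownames(X)), fast_cv(5))
  expect_gte(rs$summary$roc_auc, 0.99)

  d <- sim_xy(n = 200, p = 5, effect = 0, seed = 4)
  null_rs <- run_cv(d$X, d$y, fast_cv(10))
  expect_gt(null_rs$summary$roc_auc, 0.4)
  expect_lt(null_rs$summary$roc_auc, 0.6)
})

test_that("metric means are invariant to shuffle ordering and leakage-free", {
  d <- sim_xy(n = 100, p = 3, effect = 0.8, seed = 5)
  rs <- run_cv(d$X, d$y, fast_cv(6))
  aucs <- vapply(rs$runs, `[[`, numeric(1), "auc")
  expect_equal(mean(aucs), mean(rev(aucs)))
  # appending a sample-index column must not move null AUC materially
  d0 <- sim_xy(n = 200, p = 4, effect = 0, seed = 6)
  base <- run_cv(d0$X, d0$y, fast_cv(10))$summary$roc_auc
  Xid <- cbind(d0$X, sample_index = seq_len(nrow(d0$X)))
  leak <- run_cv(Xid, d0$y, fast_cv(10))$summary$roc_auc
  expect_lt(abs(leak - base), 0.03)
})

test_that("bind_blocks aligns on common samples and errors on mismatch", {
  m1 <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("f1", "f2")))
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("g1", "g2")))
  b1 <- feature_block(m1, "B1"); b2 <- feature_block(m2, "B2")
  X <- bind_blocks(list(b1, b2))
  expect_equal(rownames(X), c("a", "b"))
  expect_equal(colnames(X), c("f1", "f2", "g1", "g2"))
  expect_error(bind_blocks(list(b1, b2), samples = c("a", "c")), "missing")
})

test_that("importance_report applies the selection-frequency rule and 1/M baseline", {
  d <- sim_xy(n = 80, p = 4, effect = 1, seed = 7)
  rs <- run_cv(d$X, d$y, fast_cv(4))
  rep4 <- importance_report(rs)
  expect_equal(rep4$baseline, 1 / 4)
  expect_equal(rep4$n_models, 4)
  expect_true(all(rep4$table$frequency >= 0.15))

  # simulate heterogeneous selected sets: feature present in 7 of 50 models
  runs <- lapply(1:50, function(s) {
    feats <- if (s <= 7) c("f01", "rare") else "f01"
    list(shuffle = s, scores = numeric(0), auc = 0.7,
         metrics = c(sensitivity = 1, specificity = 1, mcc = 1),
         importance = stats::setNames(rep(1 / length(feats), length(feats)), feats),
         features = feats)
  })
  fake <- structure(list(label = "x", runs = runs,
                         summary = data.frame(label = "x")),
                    class = "modelrun_set")
  tab <- importance_report(fake)$table
  expect_false("rare" %in% tab$feature)  # 14% < 15%
  expect_true("f01" %in% tab$feature)
  expect_error(importance_report(list()), "empty")
})
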