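test_that("shotgun relative abundance matches the printed formula", {
  expect_equal(shotgun_relative_abundance(2000, 1000), 100)
  expect_equal(shotgun_relative_abundance(0, 5000), 0)
  expect_equal(shotgun_relative_abundance(100, 10000), 0.5)
  expect_error(shotgun_relative_abundance(10, 0), "> 0")
  # linear in read count, inversely proportional to reference size
  expect_equal(shotgun_relative_abundance(300, 1500),
               3 * shotgun_relative_abundance(100, 1500))
  expect_equal(shotgun_relative_abundance(100, 3000),
               shotgun_relative_abundance(100, 1500) / 2)
})

test_that("16S relative abundances normalize per sample", {
  expect_equal(relative_abundance_16s(c(2, 2)), c(0.5, 0.5))
  expect_equal(relative_abundance_16s(c(0, 5)), c(0, 1))
  m <- matrix(c(1, 3, 0, 0, 2, 2), 3, 2, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  expect_warning(res <- relative_abundance_16s(m), "all-zero")
  expect_equal(rowSums(res)[c(1, 3)], c(s1 = 1, s3 = 1))
  expect_true(all(is.na(res[2, ])))
  set.seed(2)
  x <- rpois(50, 3) + 1
  expect_equal(sum(relative_abundance_16s(x)), 1)
})

test_that("rank_taxa applies prevalence filter and variance ordering", {
  set.seed(4)
  n <- 20
  ab <- cbind(rare = c(rep(0.1, 4), rep(0, n - 4)),   # present in 4 < 5
              flat = rep(0.2, n),                      # zero variance
              wild = runif(n),                         # high variance
              mild = 0.5 + runif(n, 0, 0.01))
  rownames(ab) <- paste0("s", 1:n)
  r <- rank_taxa(ab, prevalence_min = 5, k = 10)
  expect_false("rare" %in% r$taxon)
  expect_equal(r$taxon[1], "wild")
  expect_equal(r$taxon[nrow(r)], "flat")       # constant taxon ranked last
  expect_message(rank_taxa(ab, k = 50), "returning all")
  expect_error(rank_taxa(ab, k = 0), "k must be")
})

test_that("binary SNP encoding follows the presence convention", {
  enc <- encode_snp_binary(c(0, 1, 2))
  expect_equal(unname(enc[, "minor_present"]), c(0, 1, 1))
  expect_equal(unname(enc[, "major_present"]), c(1, 1, 0))
  # reversible to dosage
  expect_equal(unname(enc[, 1] + (1 - enc[, 2])), c(0, 1, 2))
  expect_error(encode_snp_binary(0.5), "integral")
  expect_error(encode_snp_binary(3), "integral")
})

test_that("vif_prune removes duplicated SNPs and keeps orthogonal ones", {
  set.seed(5)
  n <- 100
  g1 <- rbinom(n, 2, 0.3)
  g2 <- rbinom(n, 2, 0.4)
  # duplicated pair alone at the degenerate threshold 1: exactly one removed
  dup <- cbind(a = g1, b = g1)
  expect_length(vif_prune(dup, window = 2, step = 1), 1)

  # at a non-degenerate threshold the independent SNP survives alongside
  geno <- cbind(a = g1, b = g1, c = g2)
  kept <- vif_prune(geno, window = 3, step = 1, vif_threshold = 2)
  expect_length(setdiff(c("a", "b"), kept), 1)  # exactly one of the pair removed
  expect_true("c" %in% kept)

  # mutually (near) orthogonal SNPs survive threshold 1
  ortho <- vapply(1:5, function(i) rbinom(n, 2, 0.5), numeric(n))
  colnames(ortho) <- paste0("s", 1:5)
  # orthogonalize exactly: residualize each column on the previous ones
  for (j in 2:5) ortho[, j] <- residuals(lm(ortho[, j] ~ ortho[, 1:(j - 1)]))
  expect_equal(vif_prune(ortho, window = 5, step = 1), colnames(ortho))

  # idempotence at fixed settings
  kept2 <- vif_prune(geno[, kept, drop = FALSE], window = 3, step = 1,
                     vif_threshold = 2)
  expect_equal(kept2, kept)
  expect_error(vif_prune(geno, window = 1), "window")
})

test_that("grs computes weighted sums and is linear", {
  dos <- matrix(c(0, 1, 2,
                  2, 0, 1), 2, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("r1", "r2", "r3")))
  def <- data.frame(snp_id = c("r1", "r2", "r3"), effect_size = c(0.1, 0.2, 0.3))
  expect_equal(unname(grs(dos, def)), c(0.8, 0.5))
  expect_equal(unname(grs(dos * 0, def)), c(0, 0))
  def0 <- def; def0$effect_size <- 0
  expect_equal(unname(grs(dos, def0)), c(0, 0))
  # linearity: grs(d, a*b1 + b2) = a*grs(d, b1) + grs(d, b2)
  set.seed(6)
  b1 <- def; b1$effect_size <- rnorm(3)
  b2 <- def; b2$effect_size <- rnorm(3)
  comb <- def; comb$effect_size <- 2.5 * b1$effect_size + b2$effect_size
  expect_equal(grs(dos, comb), 2.5 * grs(dos, b1) + grs(dos, b2),
               tolerance = 1e-12)
  expect_error(grs(dos, data.frame(snp_id = "zz", effect_size = 1)), "absent")
})

test_that("per-SNP association recovers a planted effect", {
  set.seed(7)
  n <- 500
  betas <- replicate(10, {
    g <- matrix(rbinom(n * 3, 2, 0.3), n, 3,
                dimnames = list(NULL, c("snp1", "snp2", "snp3")))
    covs <- data.frame(age = rnorm(n, 50, 8), sex = rbinom(n, 1, 0.5))
    y <- 0.5 * g[, 1] + 0.2 * covs$sex + rnorm(n)
    per_snp_association(g, y, covs, normality_alpha = 0)$beta[1]
  })
  expect_lt(abs(mean(betas) - 0.5), 0.05)
})

test_that("null genotype-phenotype p-values are approximately uniform", {
  set.seed(8)
  n <- 300
  g <- matrix(rbinom(n * 200, 2, 0.3), n, 200,
              dimnames = list(NULL, sprintf("snp%03d", 1:200)))
  y <- rnorm(n)
  res <- per_snp_association(g, y, normality_alpha = 0)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("association gates through the rank-z transform and flags monomorphic SNPs", {
  set.seed(9)
  n <- 200
  g <- cbind(mono = rep(1, n), poly = rbinom(n, 2, 0.4))
  y <- exp(rnorm(n))  # skewed: triggers the normality gate
  expect_message(res <- per_snp_association(g, y), "monomorphic")
  expect_true(is.na(res$beta[res$snp_id == "mono"]))
  expect_false(is.na(res$beta[res$snp_id == "poly"]))
  # z-transform invariance: affine rescaling of the phenotype leaves p unchanged
  res2 <- per_snp_association(g, 10 + 3 * y)
  expect_equal(res$p[2], res2$p[2], tolerance = 1e-10)
  # grs_from_association keeps only sub-threshold SNPs
  fake <- data.frame(snp_id = c("a", "b"), beta = c(1, 2), se = c(1, 1),
                     p = c(1e-6, 0.5))
  expect_equal(grs_from_association(fake)$snp_id, "a")
})
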