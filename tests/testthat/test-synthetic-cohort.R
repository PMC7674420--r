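test_that("config validation rejects bad inputs", {
  expect_error(synth_config(n_participants = 1), "n_participants")
  expect_error(synth_config(responder_sd_pct = 0), "sd values")
  expect_error(synth_config(missingness = c(Clinical = 1)), "missingness")
  expect_error(synth_config(arms = character(0)), "arms")
})

test_that("same seed gives bit-identical cohort, blocks and series", {
  cfg <- small_synth_config(seed = 9)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a, b)
  ba <- simulate_omics_blocks(cfg, a$cohort)
  bb <- simulate_omics_blocks(cfg, b$cohort)
  expect_identical(ba, bb)
  expect_identical(simulate_postprandial(cfg, a$cohort, a$truth),
                   simulate_postprandial(cfg, b$cohort, b$truth))
})

test_that("cohort has crossover structure", {
  sim <- simulate_cohort(small_synth_config())
  co <- sim$cohort
  expect_equal(nrow(co), 2 * 60)
  expect_true(all(co$w_before > 0))
  per_part <- split(co$diet_arm, co$participant_id)
  # each participant: two periods with distinct arms, one of them the control
  expect_true(all(vapply(per_part, function(a)
    length(a) == 2 && length(unique(a)) == 2 && "refined" %in% a, logical(1))))
})

test_that("class-conditional weight-change means converge to configured values", {
  cfg <- synth_config(n_participants = 11000, seed = 5,
                      missing_weight_participants = 0)
  lab <- responder_labels(simulate_cohort(cfg)$cohort)
  r <- -100 * lab$delta_w[lab$class == "responder"]
  n <- 100 * lab$delta_w[lab$class == "non_responder"]
  expect_gt(length(r), 10000)
  expect_lt(abs(mean(r[1:10000]) - 1.67), 0.1)
  expect_lt(abs(mean(n[1:10000]) - 1.39), 0.1)
  # sign always matches the class (truncation)
  expect_true(all(r > 0))
  expect_true(all(n >= 0))
})

test_that("genotype block obeys Hardy-Weinberg at fixed MAF", {
  cfg <- synth_config(n_participants = 1000, seed = 3,
                      block_sizes = c(Clinical = 2, `16S_B` = 5, MGm_B1 = 11,
                                      `LC-MS` = 5, Genotype = 40),
                      geno_maf_range = c(0.3, 0.3),
                      planted_features = NULL)
  sim <- simulate_cohort(cfg)
  geno <- simulate_omics_blocks(cfg, sim$cohort)$Genotype$values
  # one observation per participant (genotypes repeat across periods)
  geno <- geno[seq(1, nrow(geno), by = 2), ]
  freq <- table(factor(geno, levels = 0:2)) / length(geno)
  expect_lt(abs(freq[["0"]] - 0.49), 0.02)
  expect_lt(abs(freq[["1"]] - 0.42), 0.02)
  expect_lt(abs(freq[["2"]] - 0.09), 0.02)
})

test_that("rho = 1 LD blocks duplicate dosage columns", {
  cfg <- small_synth_config(seed = 4, ld_block_size = 4, ld_rho = 1)
  sim <- simulate_cohort(cfg)
  dos <- simulate_omics_blocks(cfg, sim$cohort)$Genotype$values
  expect_identical(dos[, 1], dos[, 2])
  expect_identical(dos[, 1], dos[, 4])
  expect_false(identical(dos[, 4], dos[, 5]))  # next block differs
})

test_that("planted effects separate classes; zero effects do not", {
  cfg <- synth_config(n_participants = 2000, seed = 8,
                      block_sizes = c(Clinical = 2, `16S_B` = 10, MGm_B1 = 11,
                                      `LC-MS` = 20, Genotype = 10))
  sim <- simulate_cohort(cfg)
  blocks <- simulate_omics_blocks(cfg, sim$cohort)
  resp <- sim$truth$responder == 1
  planted <- log(blocks$`LC-MS`$values[, "met_005"])
  unplanted <- log(blocks$`LC-MS`$values[, "met_020"])
  expect_gt(mean(planted[resp]) - mean(planted[!resp]), 0.05)
  expect_lt(abs(mean(unplanted[resp]) - mean(unplanted[!resp])), 0.1)
})

test_that("unknown planted features raise a configuration error", {
  cfg <- small_synth_config()
  cfg$planted_features <- data.frame(block = "LC-MS", feature = "nope",
                                     effect = 1)
  sim <- simulate_cohort(cfg)
  expect_error(simulate_omics_blocks(cfg, sim$cohort), "not in any block")
})

test_that("postprandial series have the declared lengths and class volatility", {
  cfg <- small_synth_config(seed = 2, pp_miss1 = 0, pp_miss2 = 0)
  sim <- simulate_cohort(cfg)
  pp <- simulate_postprandial(cfg, sim$cohort, sim$truth)
  lens <- tapply(pp$time_min, pp$marker, length) / nrow(sim$cohort)
  expect_equal(as.vector(lens[c("glucose", "insulin", "ffa", "glp2")]),
               rep(5, 4))                       # five blood time points
  expect_equal(as.vector(lens[["breath_h2"]]), 8)  # eight breath-H2 points
  # responders carry more volatility
  resp <- sim$truth$responder[match(unique(pp$sample_id), sim$truth$sample_id)]
  gl <- pp[pp$marker == "glucose", ]
  f1 <- vapply(unique(pp$sample_id), function(id) {
    s <- gl[gl$sample_id == id, ]
    fluc1(minmax_normalize(s$value, range(gl$value)))
  }, numeric(1))
  expect_gt(mean(f1[resp == 1]), mean(f1[resp == 0]))
})

test_that("missingness injection drops whole samples and reports complete cases", {
  cfg <- small_synth_config(seed = 6)
  sim <- simulate_cohort(cfg)
  blocks <- simulate_omics_blocks(cfg, sim$cohort)
  n <- nrow(sim$cohort)

  # all-zero fractions: complete-case N equals cohort N
  res0 <- inject_missingness(blocks, c(Clinical = 0), seed = 1)
  expect_equal(length(res0$complete_cases), n)

  # 30% of 120 observations dropped from one block -> 84 remain
  res <- inject_missingness(blocks, c(`LC-MS` = 0.3), seed = 1)
  expect_equal(nrow(res$blocks$`LC-MS`$values), n - floor(0.3 * n))

  # complete-case set is contained in every block's sample set
  resA <- inject_missingness(blocks, cfg)
  for (b in resA$blocks)
    expect_true(all(resA$complete_cases %in% rownames(b$values)))

  expect_error(inject_missingness(blocks, c(Clinical = 1)), "fractions")
})

test_that("default missingness yields a plausible complete-case subset", {
  cfg <- synth_config(seed = 10)
  sim <- simulate_cohort(cfg)
  blocks <- simulate_omics_blocks(cfg, sim$cohort)
  res <- inject_missingness(blocks, cfg)
  # ~63% of 204 observations under the default per-block drop rates
  expect_gt(length(res$complete_cases), 100)
  expect_lt(length(res$complete_cases), 160)
})

test_that("cohort and block TSV round-trips preserve values", {
  cfg <- small_synth_config()
  sim <- simulate_cohort(cfg)
  blocks <- simulate_omics_blocks(cfg, sim$cohort)
  d <- withr::local_tempdir()
  write_cohort_tsv(sim$cohort, file.path(d, "cohort.tsv"))
  back <- read_cohort_tsv(file.path(d, "cohort.tsv"))
  expect_equal(back$w_before, sim$cohort$w_before, tolerance = 1e-9)
  write_feature_block_tsv(blocks$MGm_B1, file.path(d, "mgm.tsv"))
  blk <- read_feature_block_tsv(file.path(d, "mgm.tsv"), "MGm_B1")
  expect_equal(blk$values, blocks$MGm_B1$values, tolerance = 1e-9)
})

test_that("genotype VCF export is readable and consistent", {
  skip_if_not_installed("VariantAnnotation")
  cfg <- small_synth_config(seed = 12)
  sim <- simulate_cohort(cfg)
  geno <- simulate_omics_blocks(cfg, sim$cohort)$Genotype
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  write_genotype_vcf(geno, vcf_path)
  back <- read_genotype_vcf(vcf_path)
  expect_equal(unname(back$values[rownames(geno$values), colnames(geno$values)]),
               unname(geno$values))
})
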