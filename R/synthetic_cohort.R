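#' Configuration for the synthetic crossover cohort generator
#'
#' Describes the simulated world: a two-period crossover trial in which every
#' participant consumes one active diet (whole-grain-rich or low-gluten) and
#' one refined-grain control period, with responder status driven by a
#' logistic model over diet arm and planted multi-omics effects, and relative
#' weight change drawn from class-specific truncated Gaussians whose means
#' match the observed responder (-1.67\% +/- 1.42\%) and non-responder
#' (+1.39\% +/- 1.2\%) summaries.
#'
#' @param n_participants number of participants (two baseline observations
#'   each); default 102 as in the pooled trials.
#' @param arms diet labels; the last entry is the refined-grain control.
#' @param responder_mean_pct,responder_sd_pct class-conditional mean/sd of
#'   relative weight change for responders, in percent (negative mean).
#' @param nonresponder_mean_pct,nonresponder_sd_pct same for non-responders.
#' @param diet_effect named per-arm shift in responder log-odds.
#' @param planted_features data.frame with columns `block`, `feature`,
#'   `effect` (shift in responder log-odds per SD of the latent feature).
#' @param block_sizes named integer vector of features per omics block
#'   (reduced scale by default; raise towards the full-study dimensions via
#'   this argument).
#' @param missingness named per-block fraction of samples dropped whole-sample.
#' @param intercept baseline responder log-odds.
#' @param participant_intercept_sd sd of the per-participant random intercept
#'   shared by a participant's two baselines (log-odds scale).
#' @param participant_corr fraction of latent-feature variance shared between
#'   a participant's two baselines.
#' @param geno_maf_range range minor-allele frequencies are drawn from.
#' @param ld_block_size,ld_rho genotype linkage blocks: consecutive SNPs in a
#'   block of this size share a Gaussian copula with correlation `ld_rho`.
#' @param volatility_effect relative increase of postprandial noise sd in
#'   responders (0 = no class signal in the time series).
#' @param pp_miss1,pp_miss2 probabilities that a postprandial series has
#'   exactly one / exactly two missing points.
#' @param missing_weight_participants number of participants given a missing
#'   final weight in period 2 (exercises the exclusion path; default 1).
#' @param seed master seed for the generator.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_participants = 102,
                         arms = c("whole_grain", "low_gluten", "refined"),
                         responder_mean_pct = -1.67,
                         responder_sd_pct = 1.42,
                         nonresponder_mean_pct = 1.39,
                         nonresponder_sd_pct = 1.2,
                         diet_effect = c(whole_grain = 1.2, low_gluten = 1.2,
                                         refined = 0),
                         planted_features = default_planted_features(),
                         block_sizes = c(Clinical = 8, `16S_B` = 200,
                                         MGm_B1 = 11, `LC-MS` = 100,
                                         Genotype = 500),
                         missingness = c(Clinical = 0.05, `16S_B` = 0.08,
                                         MGm_B1 = 0.08, `LC-MS` = 0.10,
                                         Genotype = 0.08, PostPran = 0.05),
                         intercept = -0.3,
                         participant_intercept_sd = 0.75,
                         participant_corr = 0.3,
                         geno_maf_range = c(0.05, 0.5),
                         ld_block_size = 1,
                         ld_rho = 0,
                         volatility_effect = 0.5,
                         pp_miss1 = 0.05,
                         pp_miss2 = 0.02,
                         missing_weight_participants = 1,
                         seed = 42) {
  if (n_participants < 2) stopf("n_participants must be >= 2")
  if (length(arms) < 1) stopf("arms must be nonempty")
  if (responder_sd_pct <= 0 || nonresponder_sd_pct <= 0)
    stopf("sd values must be > 0")
  if (any(missingness < 0) || any(missingness >= 1))
    stopf("missingness fractions must lie in [0, 1)")
  if (participant_corr < 0 || participant_corr > 1)
    stopf("participant_corr must lie in [0, 1]")
  if (responder_mean_pct >= 0 || nonresponder_mean_pct < 0)
    stopf("responder mean must be negative and non-responder mean >= 0")
  cfg <- list(n_participants = as.integer(n_participants), arms = arms,
              responder_mean_pct = responder_mean_pct,
              responder_sd_pct = responder_sd_pct,
              nonresponder_mean_pct = nonresponder_mean_pct,
              nonresponder_sd_pct = nonresponder_sd_pct,
              diet_effect = diet_effect,
              planted_features = planted_features,
              block_sizes = block_sizes,
              missingness = missingness,
              intercept = intercept,
              participant_intercept_sd = participant_intercept_sd,
              participant_corr = participant_corr,
              geno_maf_range = geno_maf_range,
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              volatility_effect = volatility_effect,
              pp_miss1 = pp_miss1, pp_miss2 = pp_miss2,
              missing_weight_participants = as.integer(missing_weight_participants),
              seed = as.integer(seed))
  structure(cfg, class = "synth_config")
}

#' Default planted effects
#'
#' A small set of butyrate-producer species, 16S taxa and urine metabolites
#' carrying responder signal, emulating the kind of features the real cohort
#' analysis found predictive. Effects are responder log-odds per latent SD.
#'
#' @return data.frame with columns `block`, `feature`, `effect`.
#' @export
default_planted_features <- function() {
  data.frame(
    block = c("MGm_B1", "MGm_B1", "MGm_B1", "16S_B", "LC-MS", "LC-MS"),
    feature = c("Faecalibacterium_prausnitzii", "Eubacterium_ramulus",
                "Roseburia_faecis", "otu_0003", "met_005", "met_017"),
    effect = c(0.8, 0.6, 0.6, 0.5, 0.7, 0.5),
    stringsAsFactors = FALSE)
}

#' Simulate a crossover cohort with planted responder effects
#'
#' Each participant contributes two baseline observations (one active-diet
#' period, one refined-grain control period, order randomised). Responder
#' status is drawn first from a logistic model over the diet arm, the planted
#' latent features and a participant random intercept; relative weight change
#' is then drawn from the class-specific Gaussian truncated at zero so the
#' sign always matches the class. The truncated distributions' location
#' parameters are calibrated so the realized class-conditional means equal
#' the configured means.
#'
#' @param config a [synth_config()].
#' @return list with elements `cohort` (a `cohort_table` data.frame:
#'   `sample_id`, `participant_id`, `period`, `diet_arm`, `w_before`,
#'   `w_after`, `age`, `sex`, `randomisation_order`; planted latents and the
#'   config are attached as attributes) and `truth` (per-sample ground-truth
#'   responder status and latent values; for validation only, never read by
#'   the pipeline).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 101))

  np <- config$n_participants
  pid <- sprintf("P%04d", seq_len(np))
  # half the participants per trial; last arm is the shared control
  active_arms <- config$arms[-length(config$arms)]
  control <- config$arms[length(config$arms)]
  trial_arm <- active_arms[1 + (seq_len(np) - 1) %% length(active_arms)]
  rand_order <- rbinom(np, 1, 0.5)   # 1 = active diet first
  age <- round(rnorm(np, 50, 8))
  sex <- rbinom(np, 1, 0.5)
  u <- rnorm(np, 0, config$participant_intercept_sd)

  obs <- data.frame(
    participant_id = rep(pid, each = 2),
    period = rep(1:2, np),
    stringsAsFactors = FALSE)
  obs$sample_id <- sprintf("%s_p%d", obs$participant_id, obs$period)
  first_active <- rep(rand_order == 1, each = 2)
  is_p1 <- obs$period == 1
  obs$diet_arm <- ifelse(first_active == is_p1, rep(trial_arm, each = 2), control)
  obs$age <- rep(age, each = 2)
  obs$sex <- rep(sex, each = 2)
  obs$randomisation_order <- rep(rand_order, each = 2)

  n_obs <- nrow(obs)
  pf <- config$planted_features
  latents <- matrix(numeric(0), nrow = n_obs, ncol = 0)
  if (!is.null(pf) && nrow(pf) > 0) {
    zp <- matrix(rnorm(np * nrow(pf)), np, nrow(pf))
    ze <- matrix(rnorm(n_obs * nrow(pf)), n_obs, nrow(pf))
    rho <- config$participant_corr
    latents <- sqrt(rho) * zp[rep(seq_len(np), each = 2), , drop = FALSE] +
      sqrt(1 - rho) * ze
    colnames(latents) <- paste(pf$block, pf$feature, sep = ":")
  }

  logit <- config$intercept +
    unname(config$diet_effect[obs$diet_arm]) +
    rep(u, each = 2)
  if (ncol(latents) > 0) logit <- logit + drop(latents %*% pf$effect)
  responder <- rbinom(n_obs, 1, stats::plogis(logit))

  mu_r <- calibrate_truncnorm_location(config$responder_mean_pct,
                                       config$responder_sd_pct)
  mu_n <- calibrate_truncnorm_location(config$nonresponder_mean_pct,
                                       config$nonresponder_sd_pct)
  dw_pct <- numeric(n_obs)
  idx_r <- which(responder == 1)
  idx_n <- which(responder == 0)
  dw_pct[idx_r] <- rtruncnorm1(length(idx_r), mu_r, config$responder_sd_pct,
                               upper = TRUE)
  dw_pct[idx_n] <- rtruncnorm1(length(idx_n), mu_n, config$nonresponder_sd_pct,
                               upper = FALSE)

  w_before <- pmax(rnorm(n_obs, 85, 12), 55)
  w_after <- w_before * (1 + dw_pct / 100)
  # exercise the missing-final-weight exclusion path
  if (config$missing_weight_participants > 0) {
    drop_pid <- pid[seq_len(min(config$missing_weight_participants, np))]
    w_after[obs$participant_id %in% drop_pid & obs$period == 2] <- NA_real_
  }

  cohort <- data.frame(sample_id = obs$sample_id,
                       participant_id = obs$participant_id,
                       period = obs$period,
                       diet_arm = obs$diet_arm,
                       w_before = w_before, w_after = w_after,
                       age = obs$age, sex = obs$sex,
                       randomisation_order = obs$randomisation_order,
                       stringsAsFactors = FALSE)
  class(cohort) <- c("cohort_table", "data.frame")
  if (ncol(latents) > 0) rownames(latents) <- cohort$sample_id
  attr(cohort, "planted_latents") <- latents
  attr(cohort, "synth_config") <- config

  truth <- data.frame(sample_id = cohort$sample_id,
                      responder = responder,
                      delta_w_pct = dw_pct,
                      logit = logit,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

# participant-correlated standard-normal latent matrix (two obs/participant)
latent_matrix <- function(n_obs, n_feat, rho) {
  np <- n_obs / 2
  zp <- matrix(rnorm(np * n_feat), np, n_feat)
  ze <- matrix(rnorm(n_obs * n_feat), n_obs, n_feat)
  sqrt(rho) * zp[rep(seq_len(np), each = 2), , drop = FALSE] +
    sqrt(1 - rho) * ze
}

#' Simulate the multi-omics feature blocks for a cohort
#'
#' Builds the Diet one-hot block plus Gaussian clinical, log-normal
#' abundance-like (16S relative abundances, shotgun butyrate-producer
#' species, LC-MS metabolite intensities) and binomial-dosage genotype
#' blocks. Planted features embed the same latent values that entered the
#' responder logit in [simulate_cohort()], so their class-conditional means
#' separate by the configured effects.
#'
#' @param config the [synth_config()] used for the cohort.
#' @param cohort the `cohort` element returned by [simulate_cohort()].
#' @return named list of [feature_block()]s: `Diet`, `Clinical`, `16S_B`,
#'   `MGm_B1`, `LC-MS`, `Genotype`. The genotype block carries SNP metadata
#'   (`chromosome`, `position`, `maf`) as attribute `snp_info`.
#' @export
simulate_omics_blocks <- function(config, cohort) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 202))
  n <- nrow(cohort)
  ids <- cohort$sample_id
  sizes <- config$block_sizes
  rho <- config$participant_corr

  feat_names <- list(
    Clinical = c("bmi", "crp", "il6", "hba1c", "homa_ir", "zonulin",
                 "sagittal_diameter", "waist")[seq_len(sizes[["Clinical"]])],
    `16S_B` = sprintf("otu_%04d", seq_len(sizes[["16S_B"]])),
    MGm_B1 = c("Faecalibacterium_prausnitzii", "Eubacterium_ramulus",
               "Roseburia_faecis", "Eubacterium_rectale", "Eubacterium_hallii",
               "Anaerostipes_hadrus", "Roseburia_intestinalis",
               "Roseburia_inulinivorans", "Butyrivibrio_crossotus",
               "Coprococcus_eutactus", "Coprococcus_catus")[seq_len(sizes[["MGm_B1"]])],
    `LC-MS` = sprintf("met_%03d", seq_len(sizes[["LC-MS"]])),
    Genotype = sprintf("snp_%05d", seq_len(sizes[["Genotype"]])))

  pf <- config$planted_features
  if (!is.null(pf) && nrow(pf) > 0) {
    known <- vapply(seq_len(nrow(pf)), function(i) {
      pf$block[i] %in% names(feat_names) &&
        pf$feature[i] %in% feat_names[[pf$block[i]]]
    }, logical(1))
    if (!all(known))
      stopf("planted feature(s) not in any block: %s",
            paste(pf$feature[!known], collapse = ", "))
  }
  latents <- attr(cohort, "planted_latents")

  plant <- function(z, label) {
    if (is.null(pf) || nrow(pf) == 0) return(z)
    sel <- which(pf$block == label)
    for (i in sel) z[, pf$feature[i]] <- latents[, paste(label, pf$feature[i],
                                                        sep = ":")]
    z
  }

  blocks <- list()

  diet <- vapply(config$arms, function(a) as.numeric(cohort$diet_arm == a),
                 numeric(n))
  colnames(diet) <- paste0("diet_", config$arms)
  rownames(diet) <- ids
  blocks$Diet <- feature_block(diet, "Diet")

  z <- latent_matrix(n, length(feat_names$Clinical), rho)
  colnames(z) <- feat_names$Clinical
  z <- plant(z, "Clinical")
  rownames(z) <- ids
  blocks$Clinical <- feature_block(z, "Clinical")

  # 16S: log-normal counts, closed to relative abundances per sample
  z <- latent_matrix(n, length(feat_names$`16S_B`), rho)
  colnames(z) <- feat_names$`16S_B`
  z <- plant(z, "16S_B")
  mu <- rnorm(ncol(z), 0, 2)          # uneven mean abundances
  ab <- exp(sweep(z, 2, mu, "+"))
  ab <- ab / rowSums(ab)
  rownames(ab) <- ids
  blocks$`16S_B` <- feature_block(ab, "16S_B")

  # shotgun butyrate producers: S_abundance-style percentages, not closed
  z <- latent_matrix(n, length(feat_names$MGm_B1), rho)
  colnames(z) <- feat_names$MGm_B1
  z <- plant(z, "MGm_B1")
  mu <- rnorm(ncol(z), -2, 1)
  ab <- exp(sweep(z, 2, mu, "+"))
  rownames(ab) <- ids
  blocks$MGm_B1 <- feature_block(ab, "MGm_B1")

  # urine metabolite intensities
  z <- latent_matrix(n, length(feat_names$`LC-MS`), rho)
  colnames(z) <- feat_names$`LC-MS`
  z <- plant(z, "LC-MS")
  mu <- rnorm(ncol(z), 8, 1.5)
  inten <- exp(sweep(z, 2, mu, "+") * 0.5)
  rownames(inten) <- ids
  blocks$`LC-MS` <- feature_block(inten, "LC-MS")

  # genotype dosages via Gaussian copula; LD blocks share copula + MAF
  p_snp <- length(feat_names$Genotype)
  bs <- max(1L, config$ld_block_size)
  block_id <- (seq_len(p_snp) - 1) %/% bs
  maf_block <- runif(max(block_id) + 1, config$geno_maf_range[1],
                     config$geno_maf_range[2])
  maf <- maf_block[block_id + 1]
  # a participant's genotype is identical at both baselines
  zp <- matrix(rnorm((n / 2) * p_snp), n / 2, p_snp)
  z <- zp[rep(seq_len(n / 2), each = 2), , drop = FALSE]
  if (config$ld_rho > 0 && bs > 1) {
    zb <- matrix(rnorm((n / 2) * (max(block_id) + 1)), n / 2, max(block_id) + 1)
    zb <- zb[rep(seq_len(n / 2), each = 2), , drop = FALSE]
    z <- sqrt(config$ld_rho) * zb[, block_id + 1, drop = FALSE] +
      sqrt(1 - config$ld_rho) * z
  }
  colnames(z) <- feat_names$Genotype
  z <- plant(z, "Genotype")
  dos <- vapply(seq_len(p_snp), function(j)
    stats::qbinom(pnorm(z[, j]), 2, maf[j]), numeric(n))
  colnames(dos) <- feat_names$Genotype
  rownames(dos) <- ids
  geno <- feature_block(dos, "Genotype")
  attr(geno, "snp_info") <- data.frame(
    snp_id = feat_names$Genotype,
    chromosome = 1L + (seq_len(p_snp) - 1L) %/% 100L,
    position = 1000L * seq_len(p_snp),
    maf = maf, stringsAsFactors = FALSE)
  blocks$Genotype <- geno

  blocks
}

#' Simulate postprandial time series for a cohort
#'
#' Four blood markers (glucose, insulin, free fatty acids, GLP-2) at
#' t = 0, 30, 60, 120, 180 min and breath hydrogen at eight half-hourly
#' points (0-210 min). Each series is a smooth meal-response curve plus
#' noise whose sd is inflated by `volatility_effect` in responders, so the
#' class signal lives in the series' volatility rather than its level.
#' Per-series missingness (exactly one or at least two missing points) is
#' injected at the configured rates.
#'
#' @param config the [synth_config()].
#' @param cohort the `cohort` element of [simulate_cohort()] (its ground
#'   truth attribute supplies class-dependent volatility).
#' @param truth the `truth` element of [simulate_cohort()].
#' @return long-format data.frame: `sample_id`, `marker`, `time_min`, `value`
#'   (NA where a point is missing).
#' @export
simulate_postprandial <- function(config, cohort, truth) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 303))
  specs <- list(
    glucose = list(times = c(0, 30, 60, 120, 180), base = 5.5, amp = 3.0, tp = 45),
    insulin = list(times = c(0, 30, 60, 120, 180), base = 60, amp = 250, tp = 40),
    ffa     = list(times = c(0, 30, 60, 120, 180), base = 0.55, amp = -0.35, tp = 90),
    glp2    = list(times = c(0, 30, 60, 120, 180), base = 15, amp = 10, tp = 60),
    breath_h2 = list(times = seq(0, 210, by = 30), base = 10, amp = 18, tp = 150))

  resp <- truth$responder[match(cohort$sample_id, truth$sample_id)]
  out <- vector("list", length(specs) * nrow(cohort))
  k <- 0
  for (m in names(specs)) {
    sp <- specs[[m]]
    shape <- (sp$times / sp$tp) * exp(1 - sp$times / sp$tp)
    nt <- length(sp$times)
    for (i in seq_len(nrow(cohort))) {
      noise_sd <- 0.12 * abs(sp$amp) * (1 + config$volatility_effect * resp[i])
      vals <- sp$base + sp$amp * shape + rnorm(nt, 0, noise_sd)
      u <- runif(1)
      if (u < config$pp_miss2) {
        vals[sample.int(nt, 2)] <- NA_real_
      } else if (u < config$pp_miss2 + config$pp_miss1) {
        vals[sample.int(nt, 1)] <- NA_real_
      }
      k <- k + 1
      out[[k]] <- data.frame(sample_id = cohort$sample_id[i], marker = m,
                             time_min = sp$times, value = vals,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Inject block-wise missingness
#'
#' Drops whole samples from each block at the configured per-block fraction
#' (count = floor(fraction x block size)), emulating participants lacking a
#' given data type, and reports the complete-case intersection.
#'
#' @param blocks named list of [feature_block()]s.
#' @param config a [synth_config()] (its `missingness` entry is used), or a
#'   named numeric vector of drop fractions keyed by block label; blocks
#'   without an entry are left untouched.
#' @param seed optional seed override (defaults to the config seed).
#' @return list with `blocks` (pruned) and `complete_cases` (sample ids
#'   present in every block).
#' @export
inject_missingness <- function(blocks, config, seed = NULL) {
  fractions <- if (inherits(config, "synth_config")) config$missingness else config
  if (any(fractions >= 1) || any(fractions < 0))
    stopf("drop fractions must lie in [0, 1)")
  base_seed <- seed %||%
    (if (inherits(config, "synth_config")) config$seed else 0L)
  set.seed(derive_seed(base_seed, 404))
  out <- blocks
  for (lab in names(blocks)) {
    fr <- fractions[lab]
    if (is.na(fr) || length(fr) == 0) next
    n <- nrow(out[[lab]]$values)
    n_drop <- floor(unname(fr) * n)
    if (n_drop > 0) {
      drop <- sample.int(n, n_drop)
      out[[lab]]$values <- out[[lab]]$values[-drop, , drop = FALSE]
    }
  }
  complete <- Reduce(intersect, lapply(out, block_samples))
  list(blocks = out, complete_cases = complete)
}

#' Write / read a cohort table as TSV
#' @param cohort a `cohort_table` data.frame.
#' @param path file path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write genotype dosages as a minimal VCF 4.2 (GT field only)
#'
#' @param geno_block the genotype [feature_block()] (dosage matrix, samples x
#'   SNPs) with an `snp_info` attribute.
#' @param path output `.vcf` path (uncompressed).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(geno_block, path) {
  dos <- geno_block$values
  info <- attr(geno_block, "snp_info")
  if (is.null(info)) stopf("genotype block lacks snp_info metadata")
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dos)), collapse = "\t")), con)
  for (j in seq_len(ncol(dos))) {
    row <- c(info$chromosome[j], info$position[j], info$snp_id[j], "A", "G",
             ".", "PASS", ".", "GT", gt[dos[, j] + 1])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}
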