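#' Shotgun species relative abundance
#'
#' For paired-end shotgun reads mapped to a reference sequence,
#' \deqn{S\_abundance = 100 \cdot ReadCount / (Size \cdot 2)}
#' where `Size` is the reference length in base pairs; linear in the read
#' count and inversely proportional to the reference size.
#'
#' @param read_count mapped read count (pairs counted as two reads).
#' @param ref_size_bp reference sequence length in bp, > 0.
#' @return relative abundance in percent.
#' @examples
#' shotgun_relative_abundance(2000, 1000)   # 100
#' shotgun_relative_abundance(100, 10000)   # 0.5
#' @export
shotgun_relative_abundance <- function(read_count, ref_size_bp) {
  if (any(ref_size_bp <= 0)) stopf("reference size must be > 0")
  if (any(read_count < 0)) stopf("read counts must be >= 0")
  100 * read_count / (ref_size_bp * 2)
}

#' 16S relative abundances for one or more samples
#'
#' Divides each taxon count by the sample's total so fractions sum to 1.
#' Samples whose counts are all zero cannot be normalized and are emitted as
#' all-`NA` rows with a warning.
#'
#' @param counts numeric vector (one sample) or matrix (samples x taxa).
#' @return fractions with the same shape as the input.
#' @export
relative_abundance_16s <- function(counts) {
  if (is.matrix(counts)) {
    tot <- rowSums(counts)
    bad <- tot == 0
    if (any(bad)) {
      warning(sum(bad), " all-zero sample(s) emitted as missing")
      tot[bad] <- NA_real_
    }
    return(sweep(counts, 1, tot, "/"))
  }
  tot <- sum(counts)
  if (tot == 0) {
    warning("all-zero sample emitted as missing")
    return(rep(NA_real_, length(counts)))
  }
  counts / tot
}

#' Rank taxa by prevalence-filtered between-visit variance
#'
#' Keeps taxa present (abundance > 0) in at least `prevalence_min` samples,
#' ranks them by the variance of their relative abundance across all visits
#' (descending), and returns the top `k`. Used to pre-select the top-10 /
#' top-250 most varying taxa as a prior-knowledge feature filter.
#'
#' @param abundance samples-by-taxa relative abundance matrix (all visits).
#' @param prevalence_min minimum number of samples a taxon must appear in.
#' @param k number of taxa to return (the whole pool, with a message, if `k`
#'   exceeds it).
#' @return data.frame `taxon`, `prevalence`, `variance`, ordered by
#'   descending variance.
#' @export
rank_taxa <- function(abundance, prevalence_min = 5, k = 10) {
  if (k <= 0) stopf("k must be >= 1")
  prev <- colSums(abundance > 0, na.rm = TRUE)
  keep <- prev >= prevalence_min
  if (!any(keep)) stopf("no taxon passes the prevalence filter")
  v <- apply(abundance[, keep, drop = FALSE], 2, var, na.rm = TRUE)
  ord <- order(v, decreasing = TRUE)
  res <- data.frame(taxon = colnames(abundance)[keep][ord],
                    prevalence = unname(prev[keep][ord]),
                    variance = unname(v[ord]),
                    stringsAsFactors = FALSE)
  if (k > nrow(res)) {
    message("k exceeds the filtered pool (", nrow(res), " taxa): returning all")
    k <- nrow(res)
  }
  res[seq_len(k), , drop = FALSE]
}

#' Binary presence encoding of a SNP dosage
#'
#' Encodes a minor-allele dosage in \{0, 1, 2\} as two indicator columns:
#' minor-allele presence (`dosage >= 1`) and major-allele presence
#' (`dosage <= 1`). The pair is reversible to the dosage.
#'
#' @param dosage integer vector of dosages in \{0, 1, 2\}.
#' @return matrix with columns `minor_present`, `major_present`.
#' @export
encode_snp_binary <- function(dosage) {
  if (any(is.na(dosage)) || any(dosage != as.integer(dosage)) ||
      any(dosage < 0 | dosage > 2))
    stopf("dosages must be integral values in {0, 1, 2}")
  cbind(minor_present = as.numeric(dosage >= 1),
        major_present = as.numeric(dosage <= 1))
}

# VIF of each column of a (centered) matrix regressed on the others
window_vifs <- function(g) {
  p <- ncol(g)
  vapply(seq_len(p), function(j) {
    y <- g[, j]
    x <- g[, -j, drop = FALSE]
    if (var(y) == 0) return(1)
    fit <- stats::lm.fit(cbind(1, x), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    r2 <- min(r2, 1 - 1e-12)
    1 / (1 - r2)
  }, numeric(1))
}

#' Sliding-window VIF pruning of SNPs
#'
#' Orders SNPs by position, slides a window of `window` SNPs advancing by
#' `step`, and inside each window iteratively removes the SNP with the
#' largest variance inflation factor (VIF = 1/(1 - R^2) of its regression on
#' the other retained window SNPs) while any VIF exceeds `vif_threshold`
#' (strict ">" with tolerance 1e-8, so mutually orthogonal SNPs survive a
#' threshold of 1). Pruning is idempotent at fixed settings.
#'
#' @param genotypes samples-by-SNPs dosage matrix.
#' @param positions SNP positions (used only for ordering); defaults to
#'   column order.
#' @param window window size in SNP count (default 50).
#' @param step window advance in SNP count (default 5).
#' @param vif_threshold VIF above which the worst SNP is removed (default 1).
#' @return character vector of retained SNP ids, in input order.
#' @export
vif_prune <- function(genotypes, positions = seq_len(ncol(genotypes)),
                      window = 50, step = 5, vif_threshold = 1) {
  if (window < 2) stopf("window must be >= 2")
  p <- ncol(genotypes)
  if (p < 2) return(colnames(genotypes))
  ord <- order(positions)
  snps <- colnames(genotypes)[ord]
  removed <- character(0)
  start <- 1
  repeat {
    win <- snps[seq(start, min(start + window - 1, p))]
    win <- setdiff(win, removed)
    while (length(win) >= 2) {
      vifs <- window_vifs(genotypes[, win, drop = FALSE])
      worst <- which.max(vifs)
      if (vifs[worst] <= vif_threshold + 1e-8) break
      removed <- c(removed, win[worst])
      win <- win[-worst]
    }
    if (start + window - 1 >= p) break
    start <- start + step
  }
  kept <- setdiff(snps, removed)
  colnames(genotypes)[colnames(genotypes) %in% kept]
}

#' Weighted genetic risk score
#'
#' Per sample, the sum of minor-allele dosages multiplied by per-SNP effect
#' sizes: \eqn{GRS = \sum_i dosage_i \cdot effect_i}. Linear in the effect
#' vector.
#'
#' @param dosages samples-by-SNPs dosage matrix with SNP colnames.
#' @param definition data.frame with columns `snp_id`, `effect_size`.
#' @return named numeric vector of scores (one per sample).
#' @export
grs <- function(dosages, definition) {
  if (nrow(definition) < 1) stopf("GRS definition must contain >= 1 SNP")
  if (anyDuplicated(definition$snp_id)) stopf("duplicate SNP ids in GRS definition")
  missing <- setdiff(definition$snp_id, colnames(dosages))
  if (length(missing) > 0)
    stopf("GRS SNP(s) absent from the genotype matrix: %s",
          paste(missing, collapse = ", "))
  drop(dosages[, definition$snp_id, drop = FALSE] %*% definition$effect_size)
}

#' Read a GRS definition from TSV
#' @param path two-column TSV (`snp_id`, `effect_size`).
#' @return data.frame usable with [grs()].
#' @export
read_grs_definition <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "effect_size") %in% names(df)))
  df
}

#' Rank-based inverse-normal (z-score) transform
#'
#' @param x numeric vector without missing values.
#' @return z-scores, \eqn{\Phi^{-1}((rank - 0.5)/n)}.
#' @export
rank_z_transform <- function(x) {
  qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Per-SNP linear association with covariate adjustment
#'
#' Fits an ordinary-least-squares model `phenotype ~ dosage + covariates`
#' for every SNP (additive coding). If a Shapiro-Wilk test rejects
#' Gaussianity of the phenotype at alpha = 0.05, the phenotype is rank-based
#' z-transformed first. Monomorphic SNPs yield `NA` estimates (with a
#' message).
#'
#' @param genotypes samples-by-SNPs dosage matrix.
#' @param phenotype numeric response vector.
#' @param covariates optional data.frame/matrix of covariates (e.g. age,
#'   sex, randomisation order), aligned with rows of `genotypes`.
#' @param normality_alpha Shapiro-Wilk significance level gating the
#'   z-transform (set to 0 to disable).
#' @return data.frame `snp_id`, `beta`, `se`, `p`.
#' @export
per_snp_association <- function(genotypes, phenotype, covariates = NULL,
                                normality_alpha = 0.05) {
  if (!is.numeric(phenotype)) stopf("phenotype must be numeric")
  y <- phenotype
  if (normality_alpha > 0 && length(unique(y)) > 3) {
    sw <- shapiro.test(if (length(y) > 5000) sample(y, 5000) else y)
    if (sw$p.value < normality_alpha) y <- rank_z_transform(y)
  }
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n_mono <- 0
  res <- lapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    if (var(g) == 0) {
      n_mono <<- n_mono + 1
      return(c(NA_real_, NA_real_, NA_real_))
    }
    X <- if (is.null(covm)) cbind(1, g) else cbind(1, g, covm)
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    df <- length(y) - fit$rank
    XtXinv <- chol2inv(chol(crossprod(X[, seq_len(fit$rank), drop = FALSE])))
    se <- sqrt(rss / df * XtXinv[2, 2])
    beta <- fit$coefficients[2]
    tval <- beta / se
    c(beta, se, 2 * stats::pt(-abs(tval), df))
  })
  if (n_mono > 0) message(n_mono, " monomorphic SNP(s) emitted as missing")
  out <- do.call(rbind, res)
  data.frame(snp_id = colnames(genotypes), beta = out[, 1], se = out[, 2],
             p = out[, 3], stringsAsFactors = FALSE)
}

#' Build GRS definitions from an association scan
#'
#' Mirrors the data-derived risk-score path: per-SNP association on a
#' delta-phenotype (intervention change minus control change), keeping SNPs
#' with p below `p_threshold` and using their estimated betas as weights.
#'
#' @param assoc data.frame from [per_snp_association()].
#' @param p_threshold inclusion threshold (default 1e-4).
#' @return a GRS definition data.frame (possibly zero rows).
#' @export
grs_from_association <- function(assoc, p_threshold = 1e-4) {
  keep <- !is.na(assoc$p) & assoc$p < p_threshold
  data.frame(snp_id = assoc$snp_id[keep], effect_size = assoc$beta[keep],
             stringsAsFactors = FALSE)
}

#' Read genotype dosages from a minimal VCF (GT field)
#'
#' Parses a VCF 4.2 file via the VariantAnnotation package (Suggests);
#' multi-allelic sites are skipped with a warning. Dosages count ALT
#' alleles.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return a [feature_block()] labelled `"Genotype"` with an `snp_info`
#'   attribute.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stopf("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  multi <- lengths(VariantAnnotation::alt(vcf)) > 1
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    vcf <- vcf[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- apply(gt, c(1, 2), function(s) {
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".")) NA_real_ else sum(a != "0")
  })
  dos <- t(dos)  # samples x SNPs
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- data.frame(snp_id = colnames(dos),
                     chromosome = as.character(GenomicRanges::seqnames(rr)),
                     position = GenomicRanges::start(rr),
                     stringsAsFactors = FALSE)
  blk <- feature_block(dos, "Genotype")
  attr(blk, "snp_info") <- info
  blk
}
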