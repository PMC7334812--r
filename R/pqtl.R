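#' Standard genotype QC: MAF and Hardy-Weinberg filters
#'
#' Removes SNPs with minor allele frequency below `maf_min` or a 1-df
#' chi-square Hardy-Weinberg test p-value below `hwe_p_min` (hard calls;
#' dosages are rounded). Removal counts are logged.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum MAF, default 0.05.
#' @param hwe_p_min minimum HWE p, default 1e-6.
#' @return the filtered [genotype_matrix()].
#' @export
hwe_maf_filter <- function(g, maf_min = 0.05, hwe_p_min = 1e-6) {
  d <- round(g$dosages)
  n0 <- colSums(d == 0); n1 <- colSums(d == 1); n2 <- colSums(d == 2)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  maf <- pmin(p, 1 - p)
  exp_counts <- cbind((1 - p)^2, 2 * p * (1 - p), p^2) * n
  obs <- cbind(n0, n1, n2)
  chi <- rowSums((obs - exp_counts)^2 / pmax(exp_counts, .Machine$double.eps))
  hwe_p <- pchisq(chi, df = 1, lower.tail = FALSE)
  hwe_p[maf == 0] <- 1                        # monomorphic: caught by MAF
  keep <- maf >= maf_min & hwe_p >= hwe_p_min
  message(sum(!keep), " of ", length(keep), " SNPs removed (",
          sum(maf < maf_min), " MAF < ", maf_min, ", ",
          sum(hwe_p < hwe_p_min & maf >= maf_min), " HWE p < ", hwe_p_min, ")")
  g$dosages <- g$dosages[, keep, drop = FALSE]
  g$snp_info <- g$snp_info[keep, , drop = FALSE]
  g$snp_info$hwe_p <- hwe_p[keep]
  g
}

#' Per-individual protein levels for the genetic scan
#'
#' The GWAS phenotype per antibody: mean of the normalized log values over
#' all of an individual's samples (all visits, duplicates included), which
#' maximizes repeatability of the trait.
#'
#' @param ds a normalized [protein_dataset()].
#' @param visit optionally restrict to a single visit.
#' @return individuals x antibodies matrix.
#' @export
individual_levels <- function(ds, visit = NULL) {
  meta <- ds$meta
  sel <- if (is.null(visit)) rep(TRUE, nrow(meta)) else meta$visit == visit
  x <- ds$intensities[sel, , drop = FALSE]
  grp <- factor(meta$individual_id[sel])
  out <- rowsum(x, grp) / as.vector(table(grp))
  out
}

#' Additive cis-pQTL linear regression scan
#'
#' Per antibody and SNP, ordinary least squares of the per-individual
#' protein level on the allele dosage (additive coding). Genome-wide
#' multiplicity is controlled by Bonferroni over the SNPs actually tested
#' (`threshold = alpha / M`). Each antibody's top SNP is annotated as cis
#' when it falls within the protein-encoding gene's window plus a margin,
#' and its LD proxies (squared dosage correlation >= `ld_min`) are
#' reported.
#'
#' @param levels individuals x antibodies matrix from
#'   [individual_levels()].
#' @param g a [genotype_matrix()] (after QC).
#' @param alpha family-wise error target, default 0.05.
#' @param target_map named antibody -> gene map for cis annotation.
#' @param cis_margin margin around the gene window in bp, default 1e6.
#' @param ld_min LD proxy cut, default 0.8.
#' @return object of class `pqtl_result`: `top` (per-antibody top SNP with
#'   effect, se, p, cis flag), `hits` (all pairs passing the threshold),
#'   `ld_proxies`, `threshold`, `m_tested`.
#' @export
pqtl_scan <- function(levels, g, alpha = 0.05, target_map = NULL,
                      cis_margin = 1e6, ld_min = 0.8) {
  ids <- intersect(rownames(levels), rownames(g$dosages))
  if (!length(ids)) stop("no overlap between phenotyped and genotyped individuals")
  if (length(ids) < 30)
    warning("fewer than 30 individuals; the scan is underpowered")
  y <- levels[ids, , drop = FALSE]
  d <- g$dosages[ids, , drop = FALSE]
  n <- length(ids)
  d0 <- scale(d, center = TRUE, scale = FALSE)
  sdg <- sqrt(colSums(d0^2) / (n - 1))
  testable <- sdg > 0
  m_tested <- sum(testable)
  threshold <- alpha / m_tested
  y0 <- scale(y, center = TRUE, scale = FALSE)
  sdy <- sqrt(colSums(y0^2) / (n - 1))
  r <- crossprod(d0[, testable, drop = FALSE], y0) /
    ((n - 1) * outer(sdg[testable], sdy))      # SNP x antibody correlations
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  beta <- r * rep(sdy, each = nrow(r)) / sdg[testable]
  se <- ifelse(tval != 0, beta / tval, NA)
  snp_ids <- colnames(d)[testable]
  top_idx <- apply(pval, 2, which.min)
  top <- data.frame(
    antibody = colnames(y),
    snp = snp_ids[top_idx],
    beta = beta[cbind(top_idx, seq_len(ncol(y)))],
    se = se[cbind(top_idx, seq_len(ncol(y)))],
    p = pval[cbind(top_idx, seq_len(ncol(y)))],
    stringsAsFactors = FALSE)
  top$significant <- top$p < threshold
  ## cis annotation
  top$cis <- NA
  if (!is.null(target_map) && !is.null(g$gene_windows)) {
    gw <- g$gene_windows
    si <- g$snp_info[match(top$snp, g$snp_info$id), ]
    wi <- gw[match(target_map[top$antibody], gw$gene), ]
    top$cis <- !is.na(wi$chrom) & si$chrom == wi$chrom &
      si$pos >= wi$start - cis_margin & si$pos <= wi$end + cis_margin
  }
  ## genome-wide significant pairs
  hit_idx <- which(pval < threshold, arr.ind = TRUE)
  hits <- data.frame(
    antibody = colnames(y)[hit_idx[, 2]],
    snp = snp_ids[hit_idx[, 1]],
    beta = beta[hit_idx], se = se[hit_idx], p = pval[hit_idx],
    stringsAsFactors = FALSE)
  ## LD proxies of significant top SNPs
  proxies <- list()
  for (i in which(top$significant)) {
    r2 <- as.vector(cor(d[, top$snp[i]], d[, testable]))^2
    sel <- which(r2 >= ld_min & snp_ids != top$snp[i])
    if (length(sel))
      proxies[[length(proxies) + 1]] <- data.frame(
        antibody = top$antibody[i], top_snp = top$snp[i],
        proxy = snp_ids[sel], r2 = r2[sel], stringsAsFactors = FALSE)
  }
  structure(list(
    top = top, hits = hits,
    ld_proxies = if (length(proxies)) do.call(rbind, proxies) else
      data.frame(),
    threshold = threshold, m_tested = m_tested, alpha = alpha,
    n_individuals = n),
    class = "pqtl_result")
}

#' @export
print.pqtl_result <- function(x, ...) {
  cat(sprintf(
    "pqtl_result: %d antibodies x %d SNPs (n = %d); Bonferroni threshold %.3g; %d significant top SNPs (%d cis)\n",
    nrow(x$top), x$m_tested, x$n_individuals, x$threshold,
    sum(x$top$significant), sum(x$top$cis & x$top$significant, na.rm = TRUE)))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param m number of tests.
#' @param alpha family-wise error rate, default 0.05.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) alpha / m

#' Squared linkage disequilibrium between two SNPs
#'
#' Genotypic r-squared: squared Pearson correlation of the dosage
#' vectors. Invariant to allele relabeling (dosage flips).
#'
#' @param g a [genotype_matrix()].
#' @param snp_a,snp_b SNP ids.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g, snp_a, snp_b) {
  a <- g$dosages[, snp_a]
  b <- g$dosages[, snp_b]
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance SNP; r2 undefined")
  cor(a, b)^2
}

#' Detect bimodal subgroups in protein levels
#'
#' Fits 1- and 2-component Gaussian mixtures (EM via `mclust`, equal and
#' unequal variance families) and selects the component count by BIC,
#' reporting the minor-subgroup fraction and per-individual assignments.
#' A distinct lower-level subgroup is the signature of genotype-dependent
#' epitope binding.
#'
#' @param x per-individual protein levels (length >= 30).
#' @return list with `n_components`, `minor_fraction`, `means`, `sds`,
#'   `assignment`, `bic`.
#' @importFrom mclust Mclust mclustBIC
#' @export
detect_level_subgroups <- function(x) {
  if (length(x) < 30) stop("subgroup detection needs >= 30 individuals")
  fit <- tryCatch(
    Mclust(x, G = 1:2, modelNames = c("E", "V"), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixture fit failed; reporting a single component")
    return(list(n_components = 1L, minor_fraction = 0,
                means = mean(x), sds = sd(x),
                assignment = rep(1L, length(x)), bic = NA_real_))
  }
  k <- fit$G
  pro <- fit$parameters$pro
  list(n_components = k,
       minor_fraction = if (k == 2) min(pro) else 0,
       means = as.numeric(fit$parameters$mean),
       sds = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
       assignment = as.integer(fit$classification),
       bic = as.numeric(fit$bic))
}
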