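make_genotypes <- function(d, chrom = NULL, pos = NULL) {
  n <- ncol(d)
  if (is.null(colnames(d))) colnames(d) <- paste0("s", seq_len(n))
  if (is.null(rownames(d))) rownames(d) <- sprintf("I%03d", seq_len(nrow(d)))
  genotype_matrix(d, data.frame(
    id = colnames(d),
    chrom = chrom %||% rep("1", n),
    pos = pos %||% (seq_len(n) * 1000),
    ref = "A", alt = "B",
    maf = pmin(colMeans(d) / 2, 1 - colMeans(d) / 2)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("MAF and HWE filters remove the right SNPs", {
  set.seed(51)
  n <- 500
  mono <- rep(0, n)                            # monomorphic
  rare <- rbinom(n, 2, 0.04)                   # MAF ~ 0.04
  het <- rep(1, n)                             # gross HWE violation
  good <- rbinom(n, 2, 0.3)
  g <- make_genotypes(cbind(mono = mono, rare = rare, het = het,
                            good = good))
  suppressMessages(out <- hwe_maf_filter(g))
  expect_identical(colnames(out$dosages), "good")
})

test_that("HWE removal rate is near its nominal level on null genotypes", {
  set.seed(52)
  g <- simulate_genotypes(400, 2000, c(0.2, 0.5))
  suppressMessages(out <- hwe_maf_filter(g, maf_min = 0, hwe_p_min = 0.05))
  removed <- 1 - ncol(out$dosages) / 2000
  expect_gt(removed, 0.02)
  expect_lt(removed, 0.09)
})

test_that("scan statistics match a per-SNP regression oracle", {
  set.seed(53)
  n <- 80
  d <- matrix(rbinom(n * 30, 2, 0.3), n, 30)
  rownames(d) <- sprintf("I%03d", seq_len(n))
  colnames(d) <- paste0("s", seq_len(30))
  g <- make_genotypes(d)
  y <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(rownames(d), c("AB1", "AB2")))
  sc <- pqtl_scan(y, g)
  for (ab in colnames(y)) {
    row <- sc$top[sc$top$antibody == ab, ]
    fit <- summary(lm(y[, ab] ~ d[, row$snp]))$coefficients
    expect_equal(row$beta, fit[2, 1], tolerance = 1e-10)
    expect_equal(row$se, fit[2, 2], tolerance = 1e-10)
    expect_equal(row$p, fit[2, 4], tolerance = 1e-10)
  }
  expect_equal(sc$threshold, 0.05 / sc$m_tested)
})

test_that("effects are scale-equivariant and p-values invariant", {
  set.seed(54)
  n <- 60
  d <- matrix(rbinom(n * 10, 2, 0.4), n, 10)
  rownames(d) <- sprintf("I%03d", seq_len(n))
  g <- make_genotypes(d)
  y <- matrix(rnorm(n), n, 1, dimnames = list(rownames(d), "AB1"))
  a <- pqtl_scan(y, g)
  b <- pqtl_scan(2 * y, g)
  expect_equal(b$top$beta, 2 * a$top$beta, tolerance = 1e-12)
  expect_equal(b$top$p, a$top$p, tolerance = 1e-12)
})

test_that("a planted cis effect is the top hit, cis-flagged, with LD proxies", {
  set.seed(55)
  n <- 101
  d <- matrix(rbinom(n * 200, 2, runif(200, 0.1, 0.5)), n, 200, byrow = TRUE)
  rownames(d) <- sprintf("I%03d", seq_len(n))
  causal <- rbinom(n, 2, 0.3)
  d[, 7] <- causal
  proxy <- causal
  flip <- runif(n) < 0.03                      # near-perfect LD copy
  proxy[flip] <- sample(0:2, sum(flip), TRUE)
  d[, 8] <- proxy
  g <- make_genotypes(d, chrom = rep(c("5", "9"), each = 100),
                      pos = rep(seq_len(100) * 1e4, 2))
  g$gene_windows <- data.frame(gene = "GENE1", chrom = "5",
                               start = 6e4, end = 9e4)
  y <- matrix(1.5 * causal + rnorm(n), n, 1,
              dimnames = list(rownames(d), "AB1"))
  sc <- pqtl_scan(y, g, target_map = c(AB1 = "GENE1"), cis_margin = 1e4)
  expect_identical(sc$top$snp, "s7")
  expect_true(sc$top$significant)
  expect_true(sc$top$cis)
  expect_true("s8" %in% sc$ld_proxies$proxy)
  expect_true(all(sc$ld_proxies$r2 >= 0.8))
  # genotype-stratified means are monotone for a positive effect
  means <- tapply(y[, 1], causal, mean)
  expect_true(all(diff(means) > 0))
})

test_that("LD r2 is exact, flip-invariant and guards degenerate SNPs", {
  d <- cbind(a = c(0, 1, 2, 2, 1, 0), b = c(2, 1, 0, 0, 1, 2),
             c = c(0, 1, 2, 1, 0, 1), mono = rep(1, 6))
  g <- make_genotypes(d)
  expect_equal(ld_r2(g, "a", "a"), 1)
  expect_equal(ld_r2(g, "a", "b"), 1)          # allele relabeling
  # hand computation: cov/sd arithmetic written out independently
  xa <- d[, "a"]; xc <- d[, "c"]
  r_hand <- sum((xa - mean(xa)) * (xc - mean(xc))) /
    sqrt(sum((xa - mean(xa))^2) * sum((xc - mean(xc))^2))
  expect_equal(ld_r2(g, "a", "c"), r_hand^2, tolerance = 1e-12)
  expect_error(ld_r2(g, "a", "mono"), "zero-variance")
})

test_that("Gaussian mixtures expose level subgroups by BIC", {
  set.seed(56)
  one <- rnorm(120)
  res1 <- detect_level_subgroups(one)
  expect_equal(res1$n_components, 1L)
  expect_equal(res1$minor_fraction, 0)

  # a 78:22 split with 4 SD separation in a 93-sample cohort
  n_lo <- 21
  two <- c(rnorm(93 - n_lo, 0, 1), rnorm(n_lo, -4, 1))
  res2 <- detect_level_subgroups(two)
  expect_equal(res2$n_components, 2L)
  expect_lt(abs(res2$minor_fraction - n_lo / 93), 0.05)

  # a 98:2 split resolvable only in a large cohort
  big <- c(rnorm(2915, 0, 1), rnorm(59, -5, 0.8))
  res3 <- detect_level_subgroups(big)
  expect_equal(res3$n_components, 2L)
  expect_lt(abs(res3$minor_fraction - 59 / 2974), 0.01)

  expect_error(detect_level_subgroups(rnorm(10)), ">= 30")
})

test_that("the genome-wide Bonferroni threshold reproduces the printed value", {
  expect_equal(signif(bonferroni_threshold(3.7e6), 3), 1.35e-8)
})
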