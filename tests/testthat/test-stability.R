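test_that("ICC(3,1) matches hand-worked and degenerate cases", {
  expect_equal(icc_3_1(cbind(1:5, 1:5)), 1)
  # consistency ignores a constant rater offset: residual mean square is 0
  expect_equal(icc_3_1(matrix(c(1, 3, 5, 2, 4, 6), ncol = 2)), 1)
  # two-way ANOVA by hand: MS_R = 10.5, MS_E = 0.5 -> 10/11
  expect_equal(icc_3_1(matrix(c(1, 3, 5, 2, 3, 7), ncol = 2)), 10 / 11)
  expect_error(icc_3_1(matrix(1:2, ncol = 2)), "at least 2")
})

test_that("ICC(3,1) agrees with a brute-force two-way ANOVA oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:12, 1); k <- sample(2:6, 1)
    m <- matrix(rnorm(n * k), n, k) + rnorm(n)
    expect_equal(icc_3_1(m), icc31_aov_oracle(m), tolerance = 1e-10)
  }
})

test_that("ICC(3,1) is invariant to rater offsets, affine maps and target order", {
  set.seed(22)
  m <- matrix(rnorm(30), 10, 3) + rnorm(10)
  base <- icc_3_1(m)
  expect_equal(icc_3_1(sweep(m, 2, c(5, -2, 0.4), "+")), base,
               tolerance = 1e-12)
  expect_equal(icc_3_1(3.7 * m - 11), base, tolerance = 1e-12)
  expect_equal(icc_3_1(m[sample(10), ]), base, tolerance = 1e-12)
})

test_that("two-rater ICC equals the paired consistency closed form", {
  set.seed(23)
  a <- rnorm(40); b <- 0.8 * a + rnorm(40, sd = 0.4)
  closed <- 2 * cov(a, b) / (var(a) + var(b))
  expect_equal(icc_3_1(cbind(a, b)), closed, tolerance = 1e-12)
})

test_that("per-visit spikes lower inter-visit but not inter-assay ICC", {
  co <- small_cohort()
  norm <- co$normalized
  icc_a <- inter_assay_icc(norm)
  icc_v <- inter_visit_icc(norm)
  spiked <- unique(subset(co$truth$deviants, criterion == "fluctuation")$antibody)
  quiet <- with(co$truth$proteins,
                antibody[sigma_tech < 0.2 & !(antibody %in% spiked)])
  # spikes are biology shared by duplicate assays: technical ICC stays high
  expect_gt(median(icc_a$icc_interassay[icc_a$antibody %in% spiked]), 0.8)
  expect_lt(median(icc_v$icc_intervisit[icc_v$antibody %in% spiked]),
            median(icc_v$icc_intervisit[icc_v$antibody %in% quiet]))
})

test_that("stability designation is recovered from the two ICC axes", {
  co <- small_cohort()
  icc_v <- inter_visit_icc(co$normalized)
  tr <- co$truth$proteins[match(icc_v$antibody, co$truth$proteins$antibody), ]
  called <- icc_v$icc_intervisit >= 0.8
  bal_acc <- mean(c(mean(called[tr$stable_true]),
                    mean(!called[!tr$stable_true])))
  expect_gt(bal_acc, 0.75)
})

test_that("classification follows the threshold rule with consistent summaries", {
  stab <- classify_stability(c(a = 0.85, b = 0.88, c = 0.4, d = 0.2),
                             c(a = 0.9, b = 0.32, c = 0.85, d = 0.1))
  expect_equal(stab$table$class,
               c("both_stable", "technical_only", "longitudinal_only",
                 "unstable"))
  expect_equal(stab$summary$technical$numerator, 2)
  expect_equal(sum(stab$summary$by_class), 4)

  # the study's printed panel counts and percentages
  icc_a <- c(rep(0.9, 447), rep(0.5, 734 - 447))
  icc_v <- c(rep(0.9, 359), rep(0.5, 447 - 359), rep(0.9, 428 - 359),
             rep(0.5, 734 - 447 - (428 - 359)))
  stab2 <- classify_stability(icc_a, icc_v)
  expect_equal(stab2$summary$technical$numerator, 447)
  expect_equal(stab2$summary$technical$percent, 61)
  expect_equal(stab2$summary$longitudinal$numerator, 428)
  expect_equal(stab2$summary$longitudinal$percent, 58)
  expect_equal(stab2$summary$both$numerator, 359)
  expect_equal(stab2$summary$both$percent, 49)
})

test_that("individuals are identifiable from their proteome signature", {
  co <- noiseless_cohort()
  idf <- individual_identifiability(log_transform(co$dataset))
  expect_equal(idf$self_match_fraction, 1)
  expect_gt(mean(idf$per_individual$icc_across_visits), 0.99)
})

test_that("without individual baselines self-matching drops to chance", {
  cfg <- small_config(sigma_bio = 0, frac_baseline = 0,
                      n_modules = 0L, frac_module = 0,
                      n_deviant_baseline = 0L, n_deviant_trend = 0L,
                      n_deviant_spike = 0L, n_seasonal = 0L,
                      n_cis_effects = 0L, n_snps = 50L)
  co <- simulate_cohort(cfg)
  norm <- suppressWarnings(normalize_pipeline(co$dataset))$dataset
  idf <- individual_identifiability(norm)
  n_samp <- cfg$n_individuals * cfg$n_visits
  se <- sqrt(idf$chance_level * (1 - idf$chance_level) / n_samp)
  expect_lt(abs(idf$self_match_fraction - idf$chance_level),
            max(4 * se, 0.05))
})

test_that("ICC is not driven by the mean intensity level", {
  co <- small_cohort()
  icc_a <- inter_assay_icc(co$normalized)
  rho <- cor(icc_a$icc_interassay, icc_a$mean_level, method = "spearman")
  expect_lt(abs(rho), 0.35)
})
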