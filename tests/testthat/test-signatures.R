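test_that("population z-scores are standardized and affine-invariant", {
  co <- small_cohort()
  pz <- population_zscore(co$normalized)
  expect_equal(unname(colMeans(pz$z)), rep(0, ncol(pz$z)), tolerance = 1e-12)
  expect_equal(unname(apply(pz$z, 2, sd)), rep(1, ncol(pz$z)),
               tolerance = 1e-12)

  shifted <- co$normalized
  shifted$intensities <- 3 * shifted$intensities + 7
  pz2 <- population_zscore(shifted)
  expect_equal(pz2$z, pz$z, tolerance = 1e-10)
})

test_that("constant proteins are excluded from z-scoring with a warning", {
  co <- small_cohort()
  ds <- co$normalized
  ds$intensities[, 1] <- 5
  expect_warning(pz <- population_zscore(ds), colnames(ds$intensities)[1])
  expect_false(colnames(ds$intensities)[1] %in% colnames(pz$z))
})

profile_fixture <- function(z_values, day_offsets) {
  z <- matrix(z_values, ncol = 1, dimnames = list(NULL, "AB1"))
  info <- data.frame(individual_id = "I1", visit = seq_along(z_values),
                     collection_date = as.Date("2015-01-01") + day_offsets)
  profile_statistics(z, info, min_visits = 2)
}

test_that("profile statistics match hand-worked ordinary least squares", {
  flat <- profile_fixture(c(1, 1, 1, 1), c(0, 80, 170, 260))
  expect_equal(flat$alpha, 1)
  expect_equal(flat$gamma, 0)
  expect_equal(flat$phi, 0)

  line <- profile_fixture(c(0, 1, 2, 3), 365.25 * (0:3))
  expect_equal(line$phi, 0, tolerance = 1e-12)
  expect_equal(line$gamma, 1, tolerance = 1e-12)

  # hand OLS on (0, 2, 0, 2) at yearly spacing:
  # slope 0.4, intercept 1 at centered time, sum |residuals| 3.2
  saw <- profile_fixture(c(0, 2, 0, 2), 365.25 * (0:3))
  expect_equal(saw$alpha, 1, tolerance = 1e-12)
  expect_equal(saw$gamma, 0.4, tolerance = 1e-12)
  expect_equal(saw$phi, 3.2, tolerance = 1e-12)
})

test_that("individuals with too few visits are excluded from profiling", {
  z <- matrix(rnorm(5), ncol = 1, dimnames = list(NULL, "AB1"))
  info <- data.frame(individual_id = c("I1", "I1", "I1", "I2", "I2"),
                     visit = c(1:3, 1:2),
                     collection_date = as.Date("2015-01-01") + c(0, 90, 180, 0, 90))
  expect_message(st <- profile_statistics(z, info), "excluding 1 individuals")
  expect_identical(unique(st$individual_id), "I1")
})

test_that("deviation flags follow the k-SD rule exactly", {
  set.seed(61)
  n <- 100
  stats <- data.frame(individual_id = sprintf("I%03d", 1:n),
                      antibody = "AB1",
                      alpha = rnorm(n), gamma = rnorm(n), phi = rnorm(n),
                      n_visits = 4)
  stats$alpha[17] <- 10
  fl <- flag_deviations(stats)
  expect_identical(which(fl$flags$baseline), 17L)
  # direct mean/SD arithmetic oracle for the flagged value
  expect_true(abs(stats$alpha[17] - mean(stats$alpha)) >
                3 * sd(stats$alpha))

  # identical individuals: zero SD, zero flags
  same <- stats
  same$alpha <- 1; same$gamma <- 1; same$phi <- 1
  w <- capture_warnings(fl0 <- flag_deviations(same))
  expect_true(length(w) > 0 && all(grepl("zero-SD", w)))
  expect_equal(sum(fl0$flags$any), 0)

  expect_equal(round(100 * fl$chance_rate, 2), 0.27)
})

test_that("flags are invariant to protein and individual order", {
  set.seed(62)
  stats <- expand.grid(individual_id = sprintf("I%02d", 1:30),
                       antibody = sprintf("AB%02d", 1:5),
                       stringsAsFactors = FALSE)
  stats$alpha <- rnorm(nrow(stats)) * 2
  stats$gamma <- rnorm(nrow(stats))
  stats$phi <- abs(rnorm(nrow(stats)))
  stats$n_visits <- 4
  a <- flag_deviations(stats)
  perm <- sample(nrow(stats))
  b <- flag_deviations(stats[perm, ])
  key <- function(f) paste(f$flags$individual_id, f$flags$antibody)
  expect_equal(b$flags$any[match(key(a), key(b))], a$flags$any)
  expect_equal(a$flagged_fraction, b$flagged_fraction)
})

test_that("inter-individual IQR separates diversity regimes", {
  # no individual signal: per-individual means shrink towards noise,
  # IQR near 2 qnorm(0.75) / sqrt(V)
  cfg <- small_config(sigma_bio = 0, frac_baseline = 0, n_modules = 0L,
                      frac_module = 0, frac_unstable = 0,
                      frac_tech_noisy = 0, n_seasonal = 0L,
                      n_deviant_baseline = 0L, n_deviant_trend = 0L,
                      n_deviant_spike = 0L, n_cis_effects = 0L,
                      n_snps = 50L, n_individuals = 60L)
  co <- simulate_cohort(cfg)
  norm <- suppressWarnings(normalize_pipeline(co$dataset))$dataset
  pz <- population_zscore(norm)
  iqr0 <- interindividual_iqr(pz$z, pz$info)
  expect_lt(abs(median(iqr0$iqr) - 2 * qnorm(0.75) / 2), 0.12)

  # strong individual baselines push the IQR towards the all-between limit
  co2 <- small_cohort()
  pz2 <- population_zscore(co2$normalized)
  iqr2 <- interindividual_iqr(pz2$z, pz2$info)
  stable <- subset(co2$truth$proteins, sigma_visit < 0.1 & module == 0 &
                     sigma_tech < 0.2)$antibody
  expect_gt(median(iqr2$iqr[iqr2$antibody %in% stable]),
            median(iqr0$iqr) + 0.3)

  # a bimodal genotype-split protein reaches the high-diversity regime
  set.seed(64)
  level <- ifelse(seq_len(60) <= 37, -0.8, 1.6)
  z_bi <- cbind(AB1 = as.vector(scale(rep(level, 4) + rnorm(240, sd = 0.3))))
  info_bi <- data.frame(individual_id = sprintf("I%03d", rep(1:60, 4)),
                        visit = rep(1:4, each = 60),
                        collection_date = as.Date("2015-01-01"))
  hi <- interindividual_iqr(z_bi, info_bi)
  expect_equal(hi$diversity, "high")

  expect_error(
    interindividual_iqr(z_bi, transform(info_bi, individual_id = "I1")),
    "more than one individual")
})

test_that("signature summaries add up, including the printed-scale grid", {
  set.seed(63)
  grid <- expand.grid(individual_id = sprintf("W%04d", 1:92),
                      antibody = sprintf("AB%03d", 1:359),
                      stringsAsFactors = FALSE)
  grid$alpha <- rnorm(nrow(grid)); grid$gamma <- rnorm(nrow(grid))
  grid$phi <- rnorm(nrow(grid)); grid$n_visits <- 4
  # one individual with planted deviations on 39/51/49 distinct proteins
  w <- grid$individual_id == "W0065"
  grid$alpha[which(w)[1:39]] <- 12
  grid$gamma[which(w)[40:90]] <- 12
  grid$phi[which(w)[91:139]] <- 12
  fl <- flag_deviations(grid)
  expect_equal(fl$n_profiles, 33028)          # 359 proteins x 92 individuals
  s <- summarize_signatures(fl)
  row <- s$per_individual[s$per_individual$individual_id == "W0065", ]
  expect_equal(row$baseline, 39)
  expect_equal(row$trend, 51)
  expect_equal(row$fluctuation, 49)
  expect_equal(row$accumulated, 139)
  expect_equal(s$overall$denominator, 33028)
  expect_equal(sum(s$venn), sum(fl$flags$any))

  # no value beyond 3 SD anywhere: all scores zero
  none <- grid
  none$alpha <- rep(c(-1, 1), length.out = nrow(none))
  none$gamma <- rep(c(-1, 0, 1), length.out = nrow(none))
  none$phi <- rep(c(0, 1), length.out = nrow(none))
  fl0 <- flag_deviations(none)
  s0 <- summarize_signatures(fl0)
  expect_equal(s0$overall$numerator, 0)
  expect_true(all(s0$per_individual$accumulated == 0))
})
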