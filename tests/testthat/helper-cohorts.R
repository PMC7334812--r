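# Shared fixture builders. Cohorts are cached per configuration key so the
# suite simulates each one once.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, maker(), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

small_config <- function(...) {
  args <- list(n_individuals = 30L, n_proteins = 40L, n_snps = 300L,
               n_modules = 2L, n_cis_effects = 3L,
               n_deviant_baseline = 5L, n_deviant_trend = 5L,
               n_deviant_spike = 5L, n_seasonal = 2L,
               plate_size = 24L, seed = 42L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

small_cohort <- function() {
  cached("small", function() {
    co <- simulate_cohort(small_config())
    co$normalized <- suppressWarnings(normalize_pipeline(co$dataset))$dataset
    co
  })
}

# all technical and visit-level noise off: only individual baselines remain
noiseless_cohort <- function() {
  cached("noiseless", function() {
    cfg <- small_config(sigma_tech = 0, frac_tech_noisy = 0, sigma_samp = 0,
                        sigma_plate = 0, sigma_visit_stable = 0,
                        frac_unstable = 0, n_modules = 0L, frac_module = 0,
                        n_seasonal = 0L, n_deviant_baseline = 0L,
                        n_deviant_trend = 0L, n_deviant_spike = 0L,
                        n_cis_effects = 0L, n_snps = 50L)
    co <- simulate_cohort(cfg)
    co$normalized <- suppressWarnings(normalize_pipeline(co$dataset))$dataset
    co
  })
}

# toy 4-sample, 3-antibody raw dataset with hand-set values
toy_dataset <- function() {
  x <- matrix(c(100, 200, 300,
                110, 210, 310,
                90, 190, 290,
                105, 205, 305), nrow = 4, byrow = TRUE,
              dimnames = list(NULL, c("AB1", "AB2", "AB3")))
  meta <- data.frame(
    sample_id = paste0("S", 1:4),
    individual_id = c("I1", "I1", "I2", "I2"),
    visit = c(1L, 2L, 1L, 2L),
    collection_date = as.Date("2015-01-01") + c(0, 90, 5, 95),
    plate_id = c("P1", "P1", "P1", "P1"),
    assay_batch = c("A1", "A2", "A1", "A2"),
    replicate_of = NA_character_,
    stringsAsFactors = FALSE)
  rownames(x) <- meta$sample_id
  protein_dataset(x, meta, scale = "raw")
}

# independent two-way ANOVA ICC(3,1) oracle built on stats::aov
icc31_aov_oracle <- function(m) {
  d <- data.frame(y = as.vector(m),
                  target = factor(rep(seq_len(nrow(m)), ncol(m))),
                  rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(aov(y ~ target + rater, data = d))[[1]]
  msr <- tab["target", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse)
}

# brute-force Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
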