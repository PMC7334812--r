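#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a wellness cohort of 101 individuals sampled at four
#' quarterly visits, profiled on ~200 antibodies with every aliquot
#' assayed in duplicate on 96-well plates. All planted effect sizes are
#' expressed in units of the protein's population SD of the log level, so
#' downstream z-score logic sees calibrated effects. Counts (seasonal
#' proteins, cis effects, deviant profiles) are drawn by inclusion, so
#' ground-truth bookkeeping matches the configuration exactly.
#'
#' @param n_individuals,n_visits,n_proteins cohort dimensions.
#' @param plate_size samples per microtiter plate.
#' @param duplicate_assay_fraction fraction of aliquots assayed twice.
#' @param seed integer seed; identical configuration implies identical
#'   output.
#' @param mu_log_range range of per-antibody mean log MFI.
#' @param sigma_bio SD of individual-specific baseline offsets (log scale).
#' @param sigma_tech per-assay technical noise SD (log scale).
#' @param frac_tech_noisy,sigma_tech_noisy fraction of antibodies with
#'   poor assay precision and their technical SD; emulates the spread of
#'   inter-assay repeatability seen across an antibody panel.
#' @param sigma_samp per-assay sample-wide scaling SD (log scale;
#'   multiplicative on the raw scale, removed by AbsPQN).
#' @param sigma_plate per-(plate, antibody) shift SD (removed by Multi-MA).
#' @param frac_baseline fraction of proteins carrying individual baselines.
#' @param frac_unstable fraction of proteins given large visit-level
#'   biological variation.
#' @param sigma_visit_stable,sigma_visit_unstable visit-level biological
#'   SD for the two groups (log scale).
#' @param n_modules,frac_module,module_loading,module_rho co-expression
#'   module count, fraction of proteins in modules, per-protein loading on
#'   the module latent trajectory (log scale) and AR(1) correlation of the
#'   latent across visits.
#' @param n_seasonal,seasonal_amplitude number of proteins with a seasonal
#'   sinusoid and its amplitude (population-SD units).
#' @param n_deviant_baseline,n_deviant_trend,n_deviant_spike number of
#'   (individual, protein) pairs planted with a persistent offset, a
#'   linear trend, or a single-visit spike.
#' @param deviant_baseline_effect,deviant_trend_effect,deviant_spike_effect
#'   planted effect sizes (population-SD units; trend is per year).
#' @param n_snps,maf_range genotype panel size and MAF range.
#' @param n_cis_effects,beta_g,cis_maf_range planted cis-pQTL count,
#'   per-allele effect (population-SD units) and MAF range of planted SNPs.
#' @param n_traits,n_trait_links,trait_link_r clinical trait count, number
#'   of traits linked to a designated protein, and the linkage correlation.
#' @param start_date,visit_spacing_days,visit_jitter_days visit calendar.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 101L, n_visits = 4L, n_proteins = 200L,
                       plate_size = 96L, duplicate_assay_fraction = 1,
                       seed = 1L,
                       mu_log_range = c(5, 9),
                       sigma_bio = 0.5, sigma_tech = 0.15,
                       frac_tech_noisy = 0.3, sigma_tech_noisy = 0.5,
                       sigma_samp = 0.2, sigma_plate = 0.3,
                       frac_baseline = 1, frac_unstable = 0.4,
                       sigma_visit_stable = 0.05, sigma_visit_unstable = 0.5,
                       n_modules = 8L, frac_module = 0.6,
                       module_loading = 0.9, module_rho = 0.9,
                       n_seasonal = 2L, seasonal_amplitude = 1,
                       n_deviant_baseline = 40L, deviant_baseline_effect = 4,
                       n_deviant_trend = 40L, deviant_trend_effect = 4,
                       n_deviant_spike = 40L, deviant_spike_effect = 5,
                       n_snps = 5000L, maf_range = c(0.05, 0.5),
                       n_cis_effects = 15L, beta_g = 1.5,
                       cis_maf_range = c(0.15, 0.45),
                       n_traits = 4L, n_trait_links = 2L, trait_link_r = 0.9,
                       start_date = as.Date("2015-01-01"),
                       visit_spacing_days = 90, visit_jitter_days = 10) {
  cfg <- as.list(environment())
  sds <- c(cfg$sigma_bio, cfg$sigma_tech, cfg$sigma_samp, cfg$sigma_plate,
           cfg$sigma_visit_stable, cfg$sigma_visit_unstable)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  fr <- c(cfg$duplicate_assay_fraction, cfg$frac_baseline, cfg$frac_unstable,
          cfg$frac_module)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$n_snps < cfg$n_cis_effects)
    stop("n_snps must be >= n_cis_effects")
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5))
    stop("maf_range must lie in (0, 0.5]")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genotype panel under Hardy-Weinberg equilibrium
#'
#' Each SNP's allele frequency is drawn uniformly from `maf_range` and
#' genotypes are Binomial(2, freq) per individual. Dosages are oriented to
#' the minor allele and the MAF recomputed from the data.
#'
#' @param n_individuals,n_snps panel dimensions.
#' @param maf_range allele-frequency range, within (0, 0.5].
#' @param seed optional seed (set for standalone use; [simulate_cohort()]
#'   manages the RNG itself).
#' @param individual_ids optional row names.
#' @return a [genotype_matrix()] without gene windows.
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               maf_range = c(0.05, 0.5), seed = NULL,
                               individual_ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(maf_range <= 0) || any(maf_range > 0.5))
    stop("maf_range must lie in (0, 0.5]")
  freq <- runif(n_snps, maf_range[1], maf_range[2])
  dosages <- matrix(rbinom(n_individuals * n_snps, 2L,
                           rep(freq, each = n_individuals)),
                    nrow = n_individuals)
  colnames(dosages) <- sprintf("snp%05d", seq_len(n_snps))
  rownames(dosages) <- if (is.null(individual_ids))
    sprintf("IND%03d", seq_len(n_individuals)) else individual_ids
  snp_info <- data.frame(
    id = colnames(dosages),
    chrom = as.character(sample.int(22L, n_snps, replace = TRUE)),
    pos = sample.int(2.5e8L, n_snps, replace = TRUE),
    ref = "A", alt = "B", maf = NA_real_, stringsAsFactors = FALSE)
  o <- orient_to_minor(dosages, snp_info)
  genotype_matrix(o$dosages, o$snp_info, NULL)
}

# mean of the AR(1) correlation matrix over V visits
ar1_mean_cor <- function(rho, V) {
  d <- abs(outer(seq_len(V), seq_len(V), "-"))
  mean(rho ^ d)
}

draw_ar1 <- function(n, V, rho) {
  f <- matrix(0, n, V)
  f[, 1] <- rnorm(n)
  if (V > 1) for (v in 2:V)
    f[, v] <- rho * f[, v - 1] + rnorm(n, sd = sqrt(1 - rho^2))
  f
}

#' Simulate a longitudinal plasma-proteomics cohort with ground truth
#'
#' Generates raw bead-array intensities for every assay sample according
#' to an additive model on the log scale: per-antibody mean level,
#' additive genotype effects at planted cis-SNPs, individual baseline
#' offsets, visit-level biological variation, seasonal sinusoids keyed to
#' the collection date, shared module trajectories (AR(1) across visits),
#' sporadic deviant profiles (persistent offsets, linear trends,
#' single-visit spikes), per-assay sample scaling, per-(plate, antibody)
#' shifts, and technical noise. Duplicate assays share all biology (the
#' aliquot) and redraw only the assay-level terms. Clinical traits are
#' generated with planted linear links to designated proteins.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (raw [protein_dataset()]),
#'   `genotypes` ([genotype_matrix()] with gene windows), `traits`
#'   (data.frame) and `truth` (ground-truth bookkeeping, class
#'   `ground_truth`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$n_individuals; V <- config$n_visits; P <- config$n_proteins
  individuals <- sprintf("IND%03d", seq_len(N))
  antibodies <- sprintf("AB%04d", seq_len(P))
  genes <- sprintf("GENE%04d", seq_len(P))
  target_map <- setNames(genes, antibodies)

  ## protein-level structure -------------------------------------------------
  mu <- runif(P, config$mu_log_range[1], config$mu_log_range[2])
  n_unstable <- round(config$frac_unstable * P)
  unstable <- rep(FALSE, P)
  unstable[sample.int(P, n_unstable)] <- TRUE
  sigma_visit <- ifelse(unstable, config$sigma_visit_unstable,
                        config$sigma_visit_stable)
  tech_noisy <- rep(FALSE, P)
  tech_noisy[sample.int(P, round(config$frac_tech_noisy * P))] <- TRUE
  sigma_tech_p <- ifelse(tech_noisy, config$sigma_tech_noisy,
                         config$sigma_tech)
  has_baseline <- rep(FALSE, P)
  has_baseline[sample.int(P, round(config$frac_baseline * P))] <- TRUE

  module <- integer(P)
  n_mod_prot <- round(config$frac_module * P)
  if (config$n_modules > 0 && n_mod_prot > 0) {
    mod_members <- sample.int(P, n_mod_prot)
    sizes <- rep(n_mod_prot %/% config$n_modules, config$n_modules)
    extra <- n_mod_prot - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    module[mod_members] <- rep(seq_len(config$n_modules), times = sizes)
  }
  loading <- ifelse(module > 0, config$module_loading, 0)

  seasonal_amp <- numeric(P)
  seasonal_phase <- numeric(P)
  if (config$n_seasonal > 0) {
    ssel <- sample.int(P, config$n_seasonal)
    seasonal_amp[ssel] <- config$seasonal_amplitude
    seasonal_phase[ssel] <- runif(config$n_seasonal, 0, 2 * pi)
  }

  # population SD of the log level (single assay, normalization-removable
  # terms excluded); planted effect sizes are multiples of this unit
  unit <- sqrt(ifelse(has_baseline, config$sigma_bio^2, 0) +
                 sigma_visit^2 + sigma_tech_p^2 + loading^2)

  ## genotypes and planted cis effects ---------------------------------------
  g <- simulate_genotypes(N, config$n_snps, config$maf_range,
                          individual_ids = individuals)
  beta_sd <- numeric(P)
  pqtl_snp <- rep(NA_character_, P)
  cis_idx <- integer(0)
  if (config$n_cis_effects > 0) {
    cis_prot <- sample.int(P, config$n_cis_effects)
    cis_idx <- sample.int(config$n_snps, config$n_cis_effects)
    cis_maf <- runif(config$n_cis_effects, config$cis_maf_range[1],
                     config$cis_maf_range[2])
    for (j in seq_along(cis_idx)) {
      g$dosages[, cis_idx[j]] <- rbinom(N, 2L, cis_maf[j])
      g$snp_info$maf[cis_idx[j]] <- mean(g$dosages[, cis_idx[j]]) / 2
    }
    beta_sd[cis_prot] <- config$beta_g
    pqtl_snp[cis_prot] <- g$snp_info$id[cis_idx]
  }
  # gene windows: one 50 kb window per gene, laid out 2 Mb apart across
  # chromosomes; planted cis-SNPs are placed inside their target window
  chrom <- as.character(rep_len(1:22, P))
  start <- 1e6 + 2e6 * (seq_len(P) %/% 22)
  gw <- data.frame(gene = genes, chrom = chrom, start = start,
                   end = start + 5e4, stringsAsFactors = FALSE)
  if (length(cis_idx)) {
    tg <- match(genes[cis_prot], gw$gene)
    g$snp_info$chrom[cis_idx] <- gw$chrom[tg]
    g$snp_info$pos[cis_idx] <- as.integer(round(runif(length(cis_idx),
                                                      gw$start[tg], gw$end[tg])))
  }
  g$gene_windows <- gw

  ## individual-level biology -------------------------------------------------
  b <- matrix(rnorm(N * P, sd = config$sigma_bio), N, P)
  b[, !has_baseline] <- 0

  first_date <- config$start_date + sample.int(365L, N, replace = TRUE) - 1L
  dates <- matrix(NA_real_, N, V)          # days since epoch
  dates[, 1] <- as.numeric(first_date)
  for (v in seq_len(V)[-1])
    dates[, v] <- as.numeric(first_date) + (v - 1) * config$visit_spacing_days +
      sample(seq(-config$visit_jitter_days, config$visit_jitter_days),
             N, replace = TRUE)

  latent <- if (config$n_modules > 0)
    lapply(seq_len(config$n_modules),
           function(m) draw_ar1(N, V, config$module_rho)) else list()

  ## deviant profiles ----------------------------------------------------------
  # total population SD of the log level including planted genotype and
  # seasonal variance; deviations are sized against what a cohort z-score
  # will actually see
  maf_p <- ifelse(is.na(pqtl_snp), 0,
                  g$snp_info$maf[match(pqtl_snp, g$snp_info$id)])
  total_sd <- unit * sqrt(1 + beta_sd^2 * 2 * maf_p * (1 - maf_p) +
                            seasonal_amp^2 / 2)
  # deviant proteins drawn without replacement, disjointly across the
  # three criteria, so planted profiles do not mask or pollute each other
  # through the population SD or through overlapping cells
  n_dev <- c(config$n_deviant_baseline, config$n_deviant_trend,
             config$n_deviant_spike)
  if (sum(n_dev) > P)
    stop("too many deviant profiles for the protein panel")
  dev_prot <- sample.int(P, sum(n_dev))
  draw_pairs <- function(prot) {
    data.frame(ind = sample.int(N, length(prot), replace = TRUE),
               prot = prot)
  }
  splits <- rep(1:3, times = n_dev)
  dev_base <- draw_pairs(dev_prot[splits == 1])
  dev_trend <- draw_pairs(dev_prot[splits == 2])
  dev_spike <- draw_pairs(dev_prot[splits == 3])
  dev_base$effect <- sample(c(-1, 1), nrow(dev_base), TRUE) *
    config$deviant_baseline_effect
  dev_trend$effect <- sample(c(-1, 1), nrow(dev_trend), TRUE) *
    config$deviant_trend_effect
  dev_spike$effect <- sample(c(-1, 1), nrow(dev_spike), TRUE) *
    config$deviant_spike_effect
  dev_spike$visit <- sample.int(V, nrow(dev_spike), replace = TRUE)

  ## biological signal per (individual, visit, protein) -----------------------
  bio <- array(0, dim = c(N, V, P))
  doy <- matrix(as.integer(format(as.Date(as.vector(dates),
                                          origin = "1970-01-01"), "%j")),
                N, V)
  years <- sweep(dates, 1, as.numeric(first_date)) / 365.25
  for (p in seq_len(P)) {
    base_p <- mu[p] + b[, p] + beta_sd[p] * unit[p] *
      (if (is.na(pqtl_snp[p])) 0 else g$dosages[, pqtl_snp[p]])
    for (v in seq_len(V)) {
      x <- base_p + rnorm(N, sd = sigma_visit[p])
      if (seasonal_amp[p] > 0)
        x <- x + seasonal_amp[p] * unit[p] *
          sin(2 * pi * doy[, v] / 365.25 + seasonal_phase[p])
      if (module[p] > 0)
        x <- x + loading[p] * latent[[module[p]]][, v]
      bio[, v, p] <- x
    }
  }
  for (r in seq_len(nrow(dev_base))) {
    i <- dev_base$ind[r]; p <- dev_base$prot[r]
    # the planted profile sits exactly at the stated offset: the planted
    # deviation replaces the individual's natural baseline and module
    # trajectory (a deviating individual is off its module's regulation)
    # rather than adding to them
    natural <- b[i, p] + if (module[p] > 0)
      loading[p] * latent[[module[p]]][i, ] else 0
    bio[i, , p] <- bio[i, , p] - natural +
      dev_base$effect[r] * total_sd[p]
  }
  for (r in seq_len(nrow(dev_trend)))
    bio[dev_trend$ind[r], , dev_trend$prot[r]] <-
      bio[dev_trend$ind[r], , dev_trend$prot[r]] +
      dev_trend$effect[r] * total_sd[dev_trend$prot[r]] *
      (years[dev_trend$ind[r], ] - mean(years[dev_trend$ind[r], ]))
  for (r in seq_len(nrow(dev_spike)))
    bio[dev_spike$ind[r], dev_spike$visit[r], dev_spike$prot[r]] <-
      bio[dev_spike$ind[r], dev_spike$visit[r], dev_spike$prot[r]] +
      dev_spike$effect[r] * total_sd[dev_spike$prot[r]]

  ## traits --------------------------------------------------------------------
  traits <- data.frame(individual_id = rep(individuals, V),
                       visit = rep(seq_len(V), each = N))
  # trait-linked proteins fluctuate within individuals (acute-phase style),
  # so the random-intercept scan sees the link in the longitudinal signal
  link_pool <- which(unstable & module == 0 & beta_sd == 0 &
                       seasonal_amp == 0 & has_baseline)
  link_prot <- integer(0)
  if (config$n_trait_links > 0) {
    link_prot <- sample(link_pool, min(config$n_trait_links, length(link_pool)))
    for (j in seq_along(link_prot)) {
      zb <- as.vector(scale(as.vector(bio[, , link_prot[j]])))
      traits[[sprintf("trait%02d", j)]] <- config$trait_link_r * zb +
        sqrt(1 - config$trait_link_r^2) * rnorm(N * V)
    }
  }
  for (j in seq(length(link_prot) + 1, length.out = config$n_traits - length(link_prot)))
    traits[[sprintf("trait%02d", j)]] <- rnorm(N * V)
  traits$sex <- rep(sample(c("F", "M"), N, replace = TRUE), V)
  traits$age <- rep(round(runif(N, 50, 65)), V)
  traits$bmi <- rep(round(rnorm(N, 25, 3.5), 1), V)

  ## assay samples: duplicates, plates, technical terms ------------------------
  aliquots <- data.frame(ind = rep(seq_len(N), V),
                         visit = rep(seq_len(V), each = N))
  n_dup <- round(config$duplicate_assay_fraction * nrow(aliquots))
  dup_sel <- sort(sample.int(nrow(aliquots), n_dup))
  samples <- rbind(cbind(aliquots, rep = 1L),
                   cbind(aliquots[dup_sel, ], rep = 2L))
  samples$sample_id <- sprintf("%s_V%d%s", individuals[samples$ind],
                               samples$visit,
                               ifelse(samples$rep == 2L, "_R", ""))
  samples$assay_batch <- sprintf("A%d_%d", samples$visit, samples$rep)
  samples$plate_id <- NA_character_
  plate_counter <- 0L
  for (ab in unique(samples$assay_batch)) {
    sel <- which(samples$assay_batch == ab)
    sel <- sel[sample.int(length(sel))]           # randomize within batch
    n_plates <- ceiling(length(sel) / config$plate_size)
    pl <- sprintf("P%03d", plate_counter + seq_len(n_plates))
    # near-equal plate fill so no plate is left with a handful of samples
    samples$plate_id[sel] <- pl[rep(seq_len(n_plates),
                                    length.out = length(sel))]
    plate_counter <- plate_counter + n_plates
  }
  plates <- sort(unique(samples$plate_id))
  delta <- matrix(rnorm(length(plates) * P, sd = config$sigma_plate),
                  length(plates), P, dimnames = list(plates, antibodies))
  csamp <- rnorm(nrow(samples), sd = config$sigma_samp)

  y <- matrix(NA_real_, nrow(samples), P,
              dimnames = list(samples$sample_id, antibodies))
  for (s in seq_len(nrow(samples)))
    y[s, ] <- bio[samples$ind[s], samples$visit[s], ] + csamp[s] +
      delta[samples$plate_id[s], ] +
      rnorm(P, sd = sigma_tech_p)

  meta <- data.frame(
    sample_id = samples$sample_id,
    individual_id = individuals[samples$ind],
    visit = samples$visit,
    collection_date = as.Date(dates[cbind(samples$ind, samples$visit)],
                              origin = "1970-01-01"),
    plate_id = samples$plate_id,
    assay_batch = samples$assay_batch,
    replicate_of = ifelse(samples$rep == 2L,
                          sprintf("%s_V%d", individuals[samples$ind],
                                  samples$visit), NA_character_),
    stringsAsFactors = FALSE)
  ds <- protein_dataset(exp(y), meta, scale = "raw", target_map = target_map)

  ## ground truth ---------------------------------------------------------------
  mean_r <- ar1_mean_cor(config$module_rho, V)
  n_assays <- 1 + config$duplicate_assay_fraction
  var_between <- ifelse(has_baseline, config$sigma_bio^2, 0) +
    loading^2 * mean_r +
    beta_sd^2 * unit^2 * 2 * ifelse(is.na(pqtl_snp), 0,
                                    g$snp_info$maf[match(pqtl_snp, g$snp_info$id)] *
                                      (1 - g$snp_info$maf[match(pqtl_snp, g$snp_info$id)]))
  var_within <- sigma_visit^2 + loading^2 * (1 - mean_r) +
    seasonal_amp^2 * unit^2 / 2 + sigma_tech_p^2 / n_assays
  icc_theory <- var_between / (var_between + var_within)
  icc_assay_theory <- (var_between + var_within - sigma_tech_p^2 / n_assays) /
    (var_between + var_within - sigma_tech_p^2 / n_assays + sigma_tech_p^2)
  proteins <- data.frame(
    antibody = antibodies, gene = genes, mu = mu, module = module,
    loading = loading, sigma_tech = sigma_tech_p, sigma_visit = sigma_visit,
    seasonal_amplitude = seasonal_amp, seasonal_phase = seasonal_phase,
    beta_sd = beta_sd, pqtl_snp = pqtl_snp, unit = unit,
    icc_theory = icc_theory, icc_assay_theory = icc_assay_theory,
    stable_true = icc_theory >= 0.8,
    stringsAsFactors = FALSE)
  deviants <- rbind(
    data.frame(individual_id = individuals[dev_base$ind],
               antibody = antibodies[dev_base$prot],
               criterion = rep("baseline", nrow(dev_base)),
               visit = rep(NA_integer_, nrow(dev_base)),
               effect = dev_base$effect),
    data.frame(individual_id = individuals[dev_trend$ind],
               antibody = antibodies[dev_trend$prot],
               criterion = rep("trend", nrow(dev_trend)),
               visit = rep(NA_integer_, nrow(dev_trend)),
               effect = dev_trend$effect),
    data.frame(individual_id = individuals[dev_spike$ind],
               antibody = antibodies[dev_spike$prot],
               criterion = rep("fluctuation", nrow(dev_spike)),
               visit = dev_spike$visit, effect = dev_spike$effect))
  pqtl_truth <- proteins[proteins$beta_sd > 0,
                         c("antibody", "gene", "pqtl_snp", "beta_sd")]
  pqtl_truth$maf <- g$snp_info$maf[match(pqtl_truth$pqtl_snp, g$snp_info$id)]
  truth <- structure(
    list(proteins = proteins, deviants = deviants, pqtl = pqtl_truth,
         baselines = b, trait_links = if (length(link_prot))
           data.frame(trait = sprintf("trait%02d", seq_along(link_prot)),
                      antibody = antibodies[link_prot]) else NULL,
         config = config),
    class = "ground_truth")
  list(dataset = ds, genotypes = g, traits = traits, truth = truth)
}
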