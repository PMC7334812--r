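#' Cohort-wide z-scores of protein profiles
#'
#' Standardizes each protein over all samples of all individuals
#' (duplicate assays averaged per visit), so that an individual's values
#' are expressed in population-SD units. Proteins with zero SD are
#' excluded with a warning.
#'
#' @param ds a normalized [protein_dataset()].
#' @param proteins optional antibody subset; typically the `both_stable`
#'   set from [classify_stability()] so the scoring focuses on profiles
#'   measured with high precision.
#' @return list with `z` (rows = individual-visit, columns = proteins)
#'   and `info` (individual, visit, collection date).
#' @export
population_zscore <- function(ds, proteins = NULL) {
  col <- collapse_assays(ds)
  x <- col$values
  if (!is.null(proteins)) x <- x[, proteins, drop = FALSE]
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("excluding zero-SD proteins: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  list(z = z, info = col$info)
}

#' Per-individual linear profile statistics
#'
#' For each individual and protein, an ordinary least-squares line is
#' fitted to the z-scored levels against time (in years, centered per
#' individual), yielding three statistics: the baseline `alpha` (fitted
#' level at the individual's mean time), the annual trend `gamma`
#' (slope), and the fluctuation `phi` (sum of absolute residuals, zero
#' for an exactly linear profile). Individuals with fewer than
#' `min_visits` visits are excluded.
#'
#' @param z,info output of [population_zscore()].
#' @param min_visits minimum visits per individual, default 3.
#' @return data.frame (class `profile_stats`) with one row per
#'   (individual, protein): `alpha`, `gamma`, `phi`, `n_visits`.
#' @export
profile_statistics <- function(z, info, min_visits = 3) {
  inds <- unique(info$individual_id)
  counts <- table(info$individual_id)
  excluded <- names(counts)[counts < min_visits]
  if (length(excluded))
    message("excluding ", length(excluded), " individuals with < ",
            min_visits, " visits")
  inds <- setdiff(inds, excluded)
  out <- vector("list", length(inds))
  for (i in seq_along(inds)) {
    sel <- info$individual_id == inds[i]
    t_years <- as.numeric(as.Date(info$collection_date[sel]))
    t_years <- (t_years - mean(t_years)) / 365.25
    y <- z[sel, , drop = FALSE]
    sxx <- sum(t_years^2)
    gamma <- as.vector(crossprod(t_years, y)) / sxx
    alpha <- colMeans(y)
    fitted <- outer(t_years, gamma) + rep(alpha, each = length(t_years))
    phi <- colSums(abs(y - fitted))
    out[[i]] <- data.frame(individual_id = inds[i],
                           antibody = colnames(z),
                           alpha = unname(alpha), gamma = unname(gamma),
                           phi = unname(phi),
                           n_visits = sum(sel), row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("profile_stats", class(res))
  res
}

#' Flag deviating baseline/trend/fluctuation statistics
#'
#' For each protein and each of the three profile statistics, an
#' individual is flagged as deviating when its value lies more than `k`
#' population SDs from the population average over individuals (mean and
#' SD include the tested individual). The expected per-criterion chance
#' rate under a Gaussian null is `2 (1 - Phi(k))`; the union rate under
#' independence is also reported.
#'
#' @param stats a `profile_stats` table.
#' @param k deviation threshold in SD units, default 3.
#' @param min_individuals proteins with fewer scored individuals are
#'   dropped with a warning (default 10).
#' @return object of class `signature_flags`: per-cell flag table,
#'   per-individual and per-protein counts, overall flagged fraction,
#'   chance rates.
#' @export
flag_deviations <- function(stats, k = 3, min_individuals = 10) {
  crits <- c(baseline = "alpha", trend = "gamma", fluctuation = "phi")
  counts <- table(stats$antibody)
  drop <- names(counts)[counts < min_individuals]
  if (length(drop)) {
    warning("dropping ", length(drop), " proteins with < ", min_individuals,
            " individuals")
    stats <- stats[!(stats$antibody %in% drop), , drop = FALSE]
  }
  flags <- stats[, c("individual_id", "antibody")]
  for (cr in names(crits)) {
    x <- stats[[crits[[cr]]]]
    mu <- ave(x, stats$antibody)
    ss <- ave(x, stats$antibody, FUN = sd)
    if (any(ss == 0))
      warning("zero-SD statistic ", crits[[cr]],
              " for some proteins; no flags there")
    flags[[cr]] <- ss > 0 & abs(x - mu) > k * ss
  }
  flags$any <- flags$baseline | flags$trend | flags$fluctuation
  per_individual <- aggregate(
    flags[, c("baseline", "trend", "fluctuation")],
    by = list(individual_id = flags$individual_id), FUN = sum)
  per_individual$accumulated <- rowSums(per_individual[, -1])
  per_protein <- aggregate(
    flags[, c("baseline", "trend", "fluctuation", "any")],
    by = list(antibody = flags$antibody), FUN = sum)
  structure(list(
    flags = flags, k = k,
    per_individual = per_individual,
    per_protein = per_protein,
    n_profiles = nrow(flags),
    flagged_fraction = mean(flags$any),
    rate_per_criterion = c(baseline = mean(flags$baseline),
                           trend = mean(flags$trend),
                           fluctuation = mean(flags$fluctuation)),
    chance_rate = chance_deviation_rate(k),
    chance_rate_union = 1 - (1 - chance_deviation_rate(k))^3),
    class = "signature_flags")
}

#' Chance rate of a +/- k SD deviation under a Gaussian null
#'
#' `2 (1 - Phi(k))`; at the conventional `k = 3` this is 0.27% per
#' criterion.
#'
#' @param k SD threshold, default 3.
#' @return two-sided Gaussian tail probability.
#' @export
chance_deviation_rate <- function(k = 3) 2 * (1 - pnorm(k))

#' @export
print.signature_flags <- function(x, ...) {
  cat(sprintf(
    "signature_flags: %d profiles; %.2f%% flagged (chance %.2f%% per criterion at +/-%g SD)\n",
    x$n_profiles, 100 * x$flagged_fraction, 100 * x$chance_rate, x$k))
  invisible(x)
}

#' Inter-individual diversity as the IQR of individual mean z-scores
#'
#' Per protein, the interquartile range across individuals of the
#' per-individual mean z-score. Illustrative cut-offs mark low-diversity
#' (`<= low`) and high-diversity (`>= high`) proteins.
#'
#' @param z,info output of [population_zscore()].
#' @param low,high cut-offs, defaults 0.15 and 1.5.
#' @return data.frame with `antibody`, `iqr`, `diversity` label.
#' @export
interindividual_iqr <- function(z, info, low = 0.15, high = 1.5) {
  if (length(unique(info$individual_id)) < 2)
    stop("IQR across individuals needs more than one individual")
  im <- rowsum(z, info$individual_id) /
    as.vector(table(info$individual_id)[sort(unique(info$individual_id))])
  iqr <- apply(im, 2, IQR)
  data.frame(antibody = colnames(z), iqr = iqr,
             diversity = ifelse(iqr <= low, "low",
                                ifelse(iqr >= high, "high", "mid")),
             row.names = NULL)
}

#' Summaries of deviation flags per individual and per protein
#'
#' Per-individual counts per criterion with the accumulated score (their
#' sum), per-protein flagged-individual counts, Venn counts of criterion
#' overlaps, and the overall flagged fraction with explicit numerator and
#' denominator.
#'
#' @param flags a `signature_flags` object.
#' @return list with `per_individual`, `per_protein`, `venn`, `overall`.
#' @export
summarize_signatures <- function(flags) {
  f <- flags$flags
  venn <- c(
    baseline_only = sum(f$baseline & !f$trend & !f$fluctuation),
    trend_only = sum(!f$baseline & f$trend & !f$fluctuation),
    fluctuation_only = sum(!f$baseline & !f$trend & f$fluctuation),
    baseline_trend = sum(f$baseline & f$trend & !f$fluctuation),
    baseline_fluctuation = sum(f$baseline & !f$trend & f$fluctuation),
    trend_fluctuation = sum(!f$baseline & f$trend & f$fluctuation),
    all_three = sum(f$baseline & f$trend & f$fluctuation))
  list(per_individual = flags$per_individual,
       per_protein = flags$per_protein,
       venn = venn,
       overall = list(numerator = sum(f$any),
                      denominator = nrow(f),
                      fraction = mean(f$any),
                      percent = round(100 * mean(f$any), 1)))
}
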