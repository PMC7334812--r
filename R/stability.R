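#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, consistency, single-measurement intraclass
#' correlation: `(MS_R - MS_E) / (MS_R + (k - 1) MS_E)`, with `MS_R` the
#' between-target mean square and `MS_E` the residual mean square after
#' removing rater means (`k` = number of raters). Consistency ICC ignores
#' systematic rater offsets. Rows with missing values are dropped;
#' negative estimates are returned as computed.
#'
#' @param m numeric matrix, rows = targets, columns = raters.
#' @return ICC(3,1) estimate in `[-1, 1]`.
#' @export
icc_3_1 <- function(m) {
  stopifnot(is.matrix(m))
  m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    stop("icc_3_1 needs at least 2 complete targets and 2 raters")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ms_r <- ss_rows / (n - 1)
  ms_e <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
}

#' Per-antibody inter-assay (technical) ICC
#'
#' Repeatability of duplicate technical assays of the same aliquot:
#' targets are aliquots (an individual's visit sample), raters are the
#' repeated assays.
#'
#' @param ds a normalized [protein_dataset()] containing duplicate assays
#'   (`replicate_of` links).
#' @return data.frame with `antibody`, `icc_interassay`, `n_aliquots`,
#'   `mean_level`.
#' @export
inter_assay_icc <- function(ds) {
  meta <- ds$meta
  dup <- which(!is.na(meta$replicate_of))
  if (!length(dup)) stop("dataset has no duplicate assays")
  orig <- match(meta$replicate_of[dup], meta$sample_id)
  ok <- !is.na(orig)
  x1 <- ds$intensities[orig[ok], , drop = FALSE]
  x2 <- ds$intensities[dup[ok], , drop = FALSE]
  icc <- vapply(seq_len(ncol(x1)), function(j)
    icc_3_1(cbind(x1[, j], x2[, j])), 0)
  data.frame(antibody = colnames(ds$intensities),
             icc_interassay = icc,
             n_aliquots = sum(ok),
             mean_level = colMeans(ds$intensities))
}

#' Per-antibody inter-visit (longitudinal) ICC
#'
#' Stability of an individual's level across visits: targets are
#' individuals, raters are visits. Duplicate assays are averaged first
#' (keeping technical and longitudinal noise sources distinct) and only
#' individuals with all visits are used by default, since the two-way
#' layout needs balanced data.
#'
#' @param ds a normalized [protein_dataset()].
#' @param complete_cases drop individuals missing any visit (default).
#' @return data.frame with `antibody`, `icc_intervisit`, `n_individuals`.
#' @export
inter_visit_icc <- function(ds, complete_cases = TRUE) {
  col <- collapse_assays(ds)
  visits <- sort(unique(col$info$visit))
  if (length(visits) < 2) stop("inter_visit_icc needs >= 2 visits")
  inds <- unique(col$info$individual_id)
  arr <- array(NA_real_, dim = c(length(inds), length(visits),
                                 ncol(col$values)))
  ri <- match(col$info$individual_id, inds)
  ci <- match(col$info$visit, visits)
  for (j in seq_len(ncol(col$values)))
    arr[cbind(ri, ci, j)] <- col$values[, j]
  keep <- apply(!is.na(arr[, , 1, drop = FALSE]), 1, all)
  if (complete_cases) {
    arr <- arr[keep, , , drop = FALSE]
    if (sum(keep) < 2) stop("fewer than 2 individuals with complete visits")
  }
  icc <- vapply(seq_len(dim(arr)[3]), function(j) icc_3_1(arr[, , j]), 0)
  data.frame(antibody = colnames(ds$intensities),
             icc_intervisit = icc,
             n_individuals = dim(arr)[1])
}

#' Classify per-protein stability from the two ICC axes
#'
#' A protein is technically consistent if its inter-assay ICC meets the
#' threshold and longitudinally stable if its inter-visit ICC does
#' (default 0.8, a conventional cut for good reliability), giving four
#' classes: `both_stable`, `technical_only`, `longitudinal_only`,
#' `unstable`.
#'
#' @param icc_a data.frame from [inter_assay_icc()] (or a numeric vector).
#' @param icc_v data.frame from [inter_visit_icc()] (or a numeric vector).
#' @param threshold ICC cut-off, default 0.8.
#' @return object of class `stability_report`: data.frame `table` plus a
#'   `summary` list of counts and fractions with explicit numerators and
#'   denominators.
#' @export
classify_stability <- function(icc_a, icc_v, threshold = 0.8) {
  if (is.data.frame(icc_a)) {
    stopifnot(identical(icc_a$antibody, icc_v$antibody))
    antibody <- icc_a$antibody
    mean_level <- icc_a$mean_level
    icc_a <- icc_a$icc_interassay
    icc_v <- icc_v$icc_intervisit
  } else {
    antibody <- names(icc_a)
    if (is.null(antibody)) antibody <- sprintf("AB%04d", seq_along(icc_a))
    mean_level <- rep(NA_real_, length(icc_a))
  }
  stopifnot(length(icc_a) == length(icc_v))
  cls <- ifelse(icc_a >= threshold,
                ifelse(icc_v >= threshold, "both_stable", "technical_only"),
                ifelse(icc_v >= threshold, "longitudinal_only", "unstable"))
  tab <- data.frame(antibody = antibody, icc_interassay = icc_a,
                    icc_intervisit = icc_v, mean_level = mean_level,
                    class = cls, stringsAsFactors = FALSE)
  n <- nrow(tab)
  frac <- function(num) list(numerator = num, denominator = n,
                             fraction = num / n,
                             percent = round(100 * num / n))
  summary <- list(
    n_antibodies = n, threshold = threshold,
    technical = frac(sum(icc_a >= threshold)),
    longitudinal = frac(sum(icc_v >= threshold)),
    both = frac(sum(cls == "both_stable")),
    by_class = table(factor(cls, levels = c("both_stable", "technical_only",
                                            "longitudinal_only", "unstable"))))
  structure(list(table = tab, summary = summary), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "stability_report: %d antibodies (ICC >= %.2f)\n  technical %d/%d (%d%%), longitudinal %d/%d (%d%%), both %d/%d (%d%%)\n",
    s$n_antibodies, s$threshold,
    s$technical$numerator, s$technical$denominator, s$technical$percent,
    s$longitudinal$numerator, s$longitudinal$denominator, s$longitudinal$percent,
    s$both$numerator, s$both$denominator, s$both$percent))
  invisible(x)
}

#' Individual identifiability of proteome signatures
#'
#' Quantifies how person-specific the multi-protein signature is. Per
#' individual, ICC(3,1) is computed with the cohort-standardized proteins
#' as targets and the visits as raters; in addition a nearest-neighbour
#' statistic reports the fraction of samples whose nearest other sample
#' (Euclidean distance on z-scored proteins, duplicates averaged) belongs
#' to the same individual. Its chance level is `(V - 1) / (N V - 1)`.
#'
#' @param ds a normalized [protein_dataset()].
#' @param min_visits individuals with fewer visits are excluded with a
#'   warning (default 2).
#' @return object of class `identifiability_report`: per-individual table,
#'   `self_match_fraction`, `chance_level`.
#' @export
individual_identifiability <- function(ds, min_visits = 2) {
  col <- collapse_assays(ds)
  z <- scale(col$values)
  keep_prot <- attr(z, "scaled:scale") > 0
  z <- z[, keep_prot, drop = FALSE]
  info <- col$info
  vis_count <- table(info$individual_id)
  drop_ind <- names(vis_count)[vis_count < min_visits]
  if (length(drop_ind))
    warning("excluding individuals with < ", min_visits, " visits: ",
            paste(drop_ind, collapse = ", "))
  inds <- setdiff(unique(info$individual_id), drop_ind)
  icc <- vapply(inds, function(id) {
    m <- t(z[info$individual_id == id, , drop = FALSE])  # proteins x visits
    icc_3_1(m)
  }, 0)
  d <- as.matrix(dist(z[info$individual_id %in% inds, , drop = FALSE]))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  own <- info$individual_id[info$individual_id %in% inds]
  self_match <- mean(own[nn] == own)
  V <- length(unique(info$visit)); N <- length(inds)
  structure(list(
    per_individual = data.frame(individual_id = inds, icc_across_visits = icc),
    self_match_fraction = self_match,
    chance_level = (V - 1) / (N * V - 1)),
    class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(sprintf(
    "identifiability_report: per-individual ICC %.3f +/- %.3f (mean +/- SD); self-match %.3f (chance %.3f)\n",
    mean(x$per_individual$icc_across_visits),
    sd(x$per_individual$icc_across_visits),
    x$self_match_fraction, x$chance_level))
  invisible(x)
}
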