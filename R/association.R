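#' Fit a random-intercept linear mixed model
#'
#' `y = X b + u[group] + e` with a Gaussian random intercept per group,
#' fitted by REML through `lmerTest` (Satterthwaite degrees of freedom for
#' the fixed effects, as is standard for longitudinal trait scans). When
#' no group has replication the random intercept is unidentifiable and the
#' fit falls back to ordinary least squares with a warning.
#'
#' @param y response vector.
#' @param x design data.frame or matrix of fixed covariates (no
#'   intercept column; one is added).
#' @param group grouping factor (individual).
#' @param reml logical, REML (default) or ML.
#' @return list with `coefficients` (data.frame: estimate, se, df, stat,
#'   p per fixed effect), `varcomp` (`sigma_b2`, `sigma2`), `fit`.
#' @export
fit_random_intercept <- function(y, x, group, reml = TRUE) {
  x <- as.data.frame(x)
  dat <- data.frame(.y = y, x, .group = factor(group), check.names = FALSE)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  terms <- setdiff(names(dat), c(".y", ".group"))
  if (length(terms)) {
    mm <- model.matrix(~ ., dat[, terms, drop = FALSE])
    if (qr(mm)$rank < ncol(mm)) stop("singular fixed-effect design")
  }
  rhs <- if (length(terms))
    paste(sprintf("`%s`", terms), collapse = " + ") else "1"
  if (max(table(dat$.group)) < 2) {
    warning("no within-group replication; falling back to OLS")
    fit <- lm(as.formula(paste(".y ~", rhs)), data = dat)
    s <- summary(fit)$coefficients
    co <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                     df = fit$df.residual, stat = s[, 3], p = s[, 4],
                     row.names = NULL)
    return(list(coefficients = co,
                varcomp = c(sigma_b2 = 0, sigma2 = summary(fit)$sigma^2),
                fit = fit))
  }
  f <- as.formula(paste(".y ~", rhs, "+ (1 | .group)"))
  fit <- suppressMessages(lmerTest::lmer(f, data = dat, REML = reml))
  s <- coef(summary(fit))
  vc <- lme4::VarCorr(fit)
  co <- data.frame(term = rownames(s), estimate = s[, "Estimate"],
                   se = s[, "Std. Error"], df = s[, "df"],
                   stat = s[, "t value"], p = s[, "Pr(>|t|)"],
                   row.names = NULL)
  list(coefficients = co,
       varcomp = c(sigma_b2 = as.numeric(vc$.group[1]),
                   sigma2 = attr(vc, "sc")^2),
       fit = fit)
}

#' Protein-trait association scan with mixed models
#'
#' For every (antibody, trait) pair, the normalized protein level
#' (duplicate assays averaged per visit) is regressed on the trait plus
#' optional fixed covariates with a random intercept per individual.
#' Benjamini-Hochberg FDR is computed over the whole protein x trait grid
#' and pairs are flagged at the configured threshold.
#'
#' @param ds a normalized [protein_dataset()].
#' @param traits trait data.frame keyed by `individual_id`, `visit`.
#' @param trait_names columns of `traits` to scan (default: all numeric
#'   columns other than keys and covariates).
#' @param covariates fixed covariate columns (e.g. sex, age, bmi);
#'   default none.
#' @param fdr_threshold significance flag level, default 0.001.
#' @param min_pairs traits with fewer non-missing pairs are skipped with
#'   a warning (default 10).
#' @return data.frame (class `association_result`) with estimate, se,
#'   Satterthwaite df, t statistic, p, FDR-adjusted p, n and flag.
#' @export
association_scan <- function(ds, traits, trait_names = NULL,
                             covariates = character(),
                             fdr_threshold = 0.001, min_pairs = 10) {
  col <- collapse_assays(ds)
  key <- paste(col$info$individual_id, col$info$visit)
  tkey <- paste(traits$individual_id, traits$visit)
  idx <- match(key, tkey)
  if (all(is.na(idx))) stop("traits do not align with the dataset")
  if (is.null(trait_names)) {
    num <- names(traits)[vapply(traits, is.numeric, TRUE)]
    trait_names <- setdiff(num, c("visit", covariates))
    trait_names <- setdiff(trait_names, "individual_id")
  }
  out <- list()
  for (tr in trait_names) {
    tv <- traits[[tr]][idx]
    if (sum(!is.na(tv)) < min_pairs || var(tv, na.rm = TRUE) == 0) {
      warning("skipping trait ", tr, " (too few pairs or constant)")
      next
    }
    covs <- traits[idx, covariates, drop = FALSE]
    for (j in seq_len(ncol(col$values))) {
      x <- data.frame(trait = tv, covs, check.names = FALSE)
      fit <- fit_random_intercept(col$values[, j], x,
                                  col$info$individual_id)
      row <- fit$coefficients[fit$coefficients$term == "trait", ]
      out[[length(out) + 1]] <- data.frame(
        antibody = colnames(col$values)[j], trait = tr,
        estimate = row$estimate, se = row$se, df = row$df,
        stat = row$stat, p = row$p, n = sum(!is.na(tv)))
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no testable traits")
  res$fdr <- p.adjust(res$p, method = "BH")
  res$significant <- res$fdr <= fdr_threshold
  class(res) <- c("association_result", class(res))
  res
}

#' Seasonal first-harmonic scan
#'
#' Fits a regular annual cycle to every protein:
#' `y ~ b_s sin(2 pi d / 365.25) + b_c cos(2 pi d / 365.25)` with a random
#' intercept per individual (`d` = day of year of the blood draw). The
#' joint 2-df test on the sine and cosine terms is a likelihood-ratio test
#' between ML fits; amplitude is `sqrt(b_s^2 + b_c^2)` and the phase is
#' reported in `[0, 2 pi)`.
#'
#' @param ds a normalized [protein_dataset()].
#' @param fdr_threshold flag level on BH-adjusted p, default 0.01.
#' @return data.frame (class `seasonal_result`) with sine/cosine
#'   coefficients, amplitude, phase, p, fdr and flag.
#' @export
seasonal_scan <- function(ds, fdr_threshold = 0.01) {
  col <- collapse_assays(ds)
  dates <- as.Date(col$info$collection_date)
  if (diff(range(dates)) < 180)
    stop("collection dates span less than 6 months; phase unidentifiable")
  d <- as.integer(format(dates, "%j"))
  sx <- sin(2 * pi * d / 365.25)
  cx <- cos(2 * pi * d / 365.25)
  grp <- factor(col$info$individual_id)
  out <- lapply(seq_len(ncol(col$values)), function(j) {
    y <- col$values[, j]
    dat <- data.frame(y = y, sx = sx, cx = cx, g = grp)
    full <- suppressMessages(lmerTest::lmer(y ~ sx + cx + (1 | g), data = dat,
                                            REML = FALSE))
    null <- suppressMessages(lmerTest::lmer(y ~ (1 | g), data = dat,
                                            REML = FALSE))
    lrt <- as.numeric(2 * (logLik(full) - logLik(null)))
    b <- lme4::fixef(full)
    amp <- sqrt(b[["sx"]]^2 + b[["cx"]]^2)
    phase <- atan2(b[["cx"]], b[["sx"]]) %% (2 * pi)
    data.frame(antibody = colnames(col$values)[j],
               b_sin = b[["sx"]], b_cos = b[["cx"]],
               amplitude = amp, phase = phase,
               p = pchisq(max(lrt, 0), df = 2, lower.tail = FALSE))
  })
  res <- do.call(rbind, out)
  res$fdr <- p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < fdr_threshold
  class(res) <- c("seasonal_result", class(res))
  res
}
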