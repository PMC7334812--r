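#' Log-transform raw intensities
#'
#' Natural log, elementwise. All statistical work downstream operates on
#' log-transformed MFI.
#'
#' @param ds a raw-scale [protein_dataset()].
#' @return the dataset on the log scale.
#' @export
log_transform <- function(ds) {
  stopifnot(inherits(ds, "protein_dataset"))
  if (ds$scale != "raw") stop("log_transform expects a raw-scale dataset")
  if (any(ds$intensities <= 0)) stop("non-positive MFI cannot be logged")
  ds$intensities <- log(ds$intensities)
  ds$scale <- "log"
  ds
}

#' Absolute probabilistic quotient normalization of one plate block
#'
#' Removes per-sample multiplicative scaling (a common dilution or
#' labelling factor) from a log-scale block: each sample's shift is the
#' median over antibodies of its difference from the column-median
#' reference profile, i.e. the log of the classical probabilistic
#' quotient. The median-shift step is iterated to its fixed point
#' (tolerance `1e-12`), which makes the operation idempotent, and the
#' block's pre-normalization grand median is restored afterwards so the
#' absolute intensity level is preserved.
#'
#' @param block log-scale matrix (samples x antibodies) from one plate.
#' @return list with `normalized` (matrix) and `factors` (per-sample
#'   raw-scale scaling factors `exp(q)` that were removed).
#' @export
abspqn <- function(block) {
  stopifnot(is.matrix(block))
  if (ncol(block) < 3)
    stop("abspqn needs at least 3 antibodies")
  grand <- median(block)
  q_total <- numeric(nrow(block))
  x <- block
  for (iter in seq_len(2000)) {
    r <- apply(x, 2, median)
    q <- apply(sweep(x, 2, r), 1, median)
    x <- x - q
    q_total <- q_total + q
    if (max(abs(q)) < 1e-13) break
  }
  x <- x + (grand - median(x))
  list(normalized = x, factors = setNames(exp(q_total), rownames(block)))
}

#' Equalize per-antibody plate means (multidimensional MA normalization)
#'
#' For each antibody, plate means are computed and every value is
#' replaced by `x - m[plate] + mean(m)`, where `mean(m)` is the unweighted
#' mean of the plate means. This is the closed form of the rotation-based
#' multidimensional MA construction: the average (A) coordinate across
#' plates is preserved and the orthogonal difference (M) components are
#' zeroed, so per-antibody plate means are equal afterwards.
#'
#' @param x log-scale matrix (samples x antibodies).
#' @param plates plate label per row.
#' @return list with `normalized` (matrix) and `offsets` (plate x antibody
#'   matrix of removed offsets, summing to zero over plates).
#' @export
multi_ma <- function(x, plates) {
  stopifnot(is.matrix(x), length(plates) == nrow(x))
  plates <- as.character(plates)
  counts <- table(plates)
  if (any(counts < 2))
    stop("plate with a single sample: ", names(counts)[counts < 2][1])
  pm <- rowsum(x, plates, reorder = TRUE) / as.vector(counts[sort(names(counts))])
  grand <- colMeans(pm)                      # unweighted mean of plate means
  offsets <- sweep(pm, 2, grand)
  out <- x - offsets[plates, , drop = FALSE]
  dimnames(out) <- dimnames(x)
  list(normalized = out, offsets = offsets)
}

# per-antibody share of variance lying between plates (one-way decomposition)
plate_variance_share <- function(x, plates) {
  plates <- as.character(plates)
  counts <- as.vector(table(plates)[sort(unique(plates))])
  pm <- rowsum(x, plates, reorder = TRUE) / counts
  grand <- colMeans(x)
  ssb <- colSums(sweep(pm, 2, grand)^2 * counts)
  sst <- colSums(sweep(x, 2, grand)^2)
  ifelse(sst > 0, ssb / sst, 0)
}

#' Full plate normalization pipeline
#'
#' Log-transforms raw MFI, applies [abspqn()] within each plate and then
#' [multi_ma()] across plates, following the by-plate normalization design
#' of bead-array studies. The audit records the per-sample scaling factors
#' removed, the per-(plate, antibody) offsets removed, and each antibody's
#' between-plate variance share before and after.
#'
#' @param ds a raw-scale [protein_dataset()] with `plate_id` set for all
#'   samples.
#' @param order `"abspqn_multima"` (default) or `"multima_abspqn"`.
#' @return list with `dataset` (normalized [protein_dataset()]) and
#'   `audit` (class `normalization_audit`).
#' @export
normalize_pipeline <- function(ds, order = c("abspqn_multima", "multima_abspqn")) {
  order <- match.arg(order)
  if (anyNA(ds$meta$plate_id)) stop("plate_id missing for some samples")
  lds <- log_transform(ds)
  x <- lds$intensities
  plates <- as.character(lds$meta$plate_id)
  share_before <- plate_variance_share(x, plates)

  run_abspqn <- function(x) {
    factors <- numeric(nrow(x))
    for (pl in unique(plates)) {
      sel <- plates == pl
      res <- abspqn(x[sel, , drop = FALSE])
      x[sel, ] <- res$normalized
      factors[sel] <- res$factors
    }
    list(x = x, factors = factors)
  }
  if (order == "abspqn_multima") {
    a <- run_abspqn(x)
    m <- multi_ma(a$x, plates)
    x <- m$normalized
  } else {
    m <- multi_ma(x, plates)
    a <- run_abspqn(m$normalized)
    x <- a$x
  }
  share_after <- plate_variance_share(x, plates)

  out <- lds
  out$intensities <- x
  out$scale <- "normalized"
  audit <- structure(
    list(sample_factors = data.frame(sample_id = lds$meta$sample_id,
                                     plate_id = plates,
                                     abspqn_factor = a$factors),
         plate_offsets = m$offsets,
         variance_share = data.frame(antibody = colnames(x),
                                     share_before = share_before,
                                     share_after = share_after),
         order = order),
    class = "normalization_audit")
  list(dataset = out, audit = audit)
}

#' @export
print.normalization_audit <- function(x, ...) {
  cat("normalization_audit:", nrow(x$sample_factors), "samples,",
      nrow(x$plate_offsets), "plates; median between-plate variance share",
      sprintf("%.3f -> %.3f", median(x$variance_share$share_before),
              median(x$variance_share$share_after)), "\n")
  invisible(x)
}
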