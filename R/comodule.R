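#' Pick the soft-threshold power for a correlation network
#'
#' Chooses the smallest power whose unsigned adjacency gives approximate
#' scale-free topology: connectivities are binned, and the fit index is
#' the R-squared of a linear fit of `log10 p(k)` on `log10 k` (counted
#' only when the slope is negative). Falls back to the power with the
#' best fit, with a warning, when no candidate reaches the cut.
#'
#' @param expr individuals x proteins matrix.
#' @param candidates candidate powers, default `1:20`.
#' @param rsq_cut scale-free fit threshold, default 0.8.
#' @param n_bins connectivity histogram bins, default 10.
#' @return selected power (integer), with the fit table in attribute
#'   `"fit"`.
#' @export
pick_soft_power <- function(expr, candidates = 1:20, rsq_cut = 0.8,
                            n_bins = 10) {
  cc <- cor(expr)
  if (anyNA(cc)) stop("degenerate correlation matrix (constant protein?)")
  acc <- abs(cc); diag(acc) <- 0
  rsq <- vapply(candidates, function(beta) {
    k <- rowSums(acc ^ beta)
    if (sd(k) == 0) return(1)                  # degenerate: trivially scale-free
    if (max(k) < 1) return(0)                  # empty network: fit meaningless
    br <- cut(k, breaks = n_bins)
    pk <- as.vector(table(br)) / length(k)
    km <- tapply(k, br, mean)
    keep <- pk > 0 & !is.na(km) & km > 0
    if (sum(keep) < 3) return(0)
    fit <- lm(log10(pk[keep]) ~ log10(km[keep]))
    r2 <- summary(fit)$r.squared
    if (coef(fit)[2] > 0) 0 else r2
  }, 0)
  ok <- which(rsq >= rsq_cut)
  if (length(ok)) {
    beta <- candidates[ok[1]]
  } else {
    warning("no candidate power reaches scale-free fit ", rsq_cut,
            "; using the best fit")
    beta <- candidates[which.max(rsq)]
  }
  attr(beta, "fit") <- data.frame(power = candidates, rsq = rsq)
  beta
}

#' Unsigned adjacency and topological overlap matrix
#'
#' Adjacency `a_ij = |cor(i, j)|^beta`; topological overlap
#' `w_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `w_ii = 1`, rewarding shared network neighbours. The clustering
#' dissimilarity is `1 - w`.
#'
#' @param expr individuals x proteins matrix.
#' @param beta soft-threshold power (>= 1).
#' @return list with `adjacency` and `tom` matrices.
#' @export
adjacency_tom <- function(expr, beta) {
  stopifnot(beta >= 1)
  sds <- apply(expr, 2, sd)
  if (any(sds == 0))
    stop("constant protein: ", colnames(expr)[which(sds == 0)[1]])
  a <- abs(cor(expr)) ^ beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  w <- num / den
  diag(w) <- 1
  dimnames(w) <- dimnames(a) <- list(colnames(expr), colnames(expr))
  list(adjacency = a, tom = w)
}

module_eigengene <- function(expr, members) {
  sub <- scale(expr[, members, drop = FALSE])
  pc <- prcomp(sub, center = FALSE, scale. = FALSE)$x[, 1]
  pc <- pc / sd(pc)
  if (mean(cor(pc, sub)) < 0) pc <- -pc
  pc
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on `1 - TOM` with a static cut;
#' clusters smaller than `min_size` are left unassigned (label 0). Module
#' eigengenes (first principal component of the standardized member
#' submatrix, unit variance, oriented so the mean member correlation is
#' positive) are computed, and modules whose eigengenes correlate above
#' `merge_cor` are merged iteratively. Final labels are 1..K by
#' decreasing size.
#'
#' @param tom TOM similarity matrix (from [adjacency_tom()]).
#' @param expr individuals x proteins matrix used for eigengenes.
#' @param min_size minimum module size, default 10.
#' @param cut_height static tree-cut height on `1 - TOM`, default 0.8.
#' @param merge_cor eigengene correlation above which modules merge,
#'   default 0.8.
#' @param visit optional visit index carried in the result.
#' @return object of class `visit_modules`: `labels` (named integer,
#'   0 = unassigned), `eigengenes` (individuals x modules), `sizes`,
#'   `visit`.
#' @export
detect_modules <- function(tom, expr, min_size = 10, cut_height = 0.8,
                           merge_cor = 0.8, visit = NA_integer_) {
  stopifnot(nrow(tom) == ncol(tom), ncol(expr) == ncol(tom))
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  labels <- ifelse(sizes[as.character(raw)] >= min_size, raw, 0L)
  names(labels) <- colnames(tom)
  mods <- setdiff(unique(labels), 0L)
  if (!length(mods)) {
    warning("no module reaches min_size; all proteins unassigned")
    return(structure(list(labels = labels * 0L,
                          eigengenes = NULL, sizes = integer(0),
                          visit = visit), class = "visit_modules"))
  }
  members <- lapply(mods, function(m) which(labels == m))
  repeat {
    eg <- vapply(members, function(mm) module_eigengene(expr, mm),
                 numeric(nrow(expr)))
    if (length(members) < 2) break
    cc <- cor(eg); diag(cc) <- 0
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= merge_cor) break
    members[[mx[1]]] <- sort(c(members[[mx[1]]], members[[mx[2]]]))
    members[[mx[2]]] <- NULL
  }
  ord <- order(vapply(members, length, 0L), decreasing = TRUE)
  members <- members[ord]
  labels[] <- 0L
  for (m in seq_along(members)) labels[members[[m]]] <- m
  eg <- vapply(members, function(mm) module_eigengene(expr, mm),
               numeric(nrow(expr)))
  colnames(eg) <- paste0("M", seq_along(members))
  rownames(eg) <- rownames(expr)
  structure(list(labels = labels, eigengenes = eg,
                 sizes = vapply(members, length, 0L), visit = visit),
            class = "visit_modules")
}

#' @export
print.visit_modules <- function(x, ...) {
  cat("visit_modules (visit ", x$visit, "): ", length(x$sizes),
      " modules of sizes ", paste(x$sizes, collapse = ", "),
      "; ", sum(x$labels == 0), " unassigned\n", sep = "")
  invisible(x)
}

#' Per-visit module detection for a longitudinal dataset
#'
#' Convenience wrapper running [pick_soft_power()], [adjacency_tom()] and
#' [detect_modules()] on each visit's individuals x proteins matrix
#' (duplicates averaged).
#'
#' @param ds a normalized [protein_dataset()].
#' @param ... passed to [detect_modules()].
#' @param power soft-threshold power. The default 2 keeps the topological
#'   overlap of genuinely co-varying proteins well separated from the
#'   background on panels of a few hundred proteins, which the fixed-height
#'   tree cut requires; set `power = NULL` to select it per visit with
#'   [pick_soft_power()] (scale-free fit, appropriate for much larger
#'   networks).
#' @return list of `visit_modules`, one per visit.
#' @export
modules_per_visit <- function(ds, power = 2, ...) {
  col <- collapse_assays(ds)
  visits <- sort(unique(col$info$visit))
  lapply(visits, function(v) {
    expr <- col$values[col$info$visit == v, , drop = FALSE]
    beta <- if (is.null(power))
      suppressWarnings(pick_soft_power(expr)) else power
    at <- adjacency_tom(expr, beta)
    detect_modules(at$tom, expr, visit = v, ...)
  })
}

#' Match modules across visits into core patterns
#'
#' For each consecutive pair of visits, modules are matched one-to-one by
#' maximal Jaccard overlap of their membership sets (greedy in descending
#' overlap; ties broken by the larger earlier-visit module, then by the
#' lower label). Chains of matched modules spanning every visit define
#' candidate core patterns; a protein belongs to a core pattern only if it
#' sits in the chain's module at every visit. Matching operates on
#' membership sets, so the result does not depend on module numbering.
#'
#' @param vm_list list of `visit_modules` over the same protein universe.
#' @param min_core_size smallest retained core pattern, default 5.
#' @return object of class `core_module_assignment`: per-protein label
#'   sequence and core id, per-pattern chain and size, assigned fraction.
#' @export
match_core_modules <- function(vm_list, min_core_size = 5) {
  stopifnot(length(vm_list) >= 2)
  prot <- names(vm_list[[1]]$labels)
  for (vm in vm_list)
    if (!length(intersect(prot, names(vm$labels))))
      stop("visits have disjoint protein sets")
  for (vm in vm_list) stopifnot(setequal(prot, names(vm$labels)))
  labels <- vapply(vm_list, function(vm) vm$labels[prot], integer(length(prot)))
  V <- ncol(labels)
  # greedy 1-1 matching between consecutive visits
  links <- vector("list", V - 1)
  for (v in seq_len(V - 1)) {
    m1 <- setdiff(unique(labels[, v]), 0L)
    m2 <- setdiff(unique(labels[, v + 1]), 0L)
    if (!length(m1) || !length(m2)) { links[[v]] <- integer(0); next }
    cand <- expand.grid(a = m1, b = m2)
    cand$jac <- mapply(function(a, b) {
      sa <- labels[, v] == a; sb <- labels[, v + 1] == b
      sum(sa & sb) / sum(sa | sb)
    }, cand$a, cand$b)
    cand$size_a <- vapply(cand$a, function(a) sum(labels[, v] == a), 0L)
    cand <- cand[order(-cand$jac, -cand$size_a, cand$a, cand$b), ]
    cand <- cand[cand$jac > 0, , drop = FALSE]
    link <- integer(0)
    used_b <- integer(0)
    for (r in seq_len(nrow(cand))) {
      a <- cand$a[r]; b <- cand$b[r]
      if (as.character(a) %in% names(link)) next
      if (b %in% used_b) next
      link[as.character(a)] <- b
      used_b <- c(used_b, b)
    }
    links[[v]] <- link
  }
  # chains starting at visit-1 modules and spanning all visits
  chains <- list()
  for (m in setdiff(unique(labels[, 1]), 0L)) {
    chain <- m
    ok <- TRUE
    for (v in seq_len(V - 1)) {
      nxt <- links[[v]][as.character(chain[v])]
      if (is.na(nxt) || !length(nxt)) { ok <- FALSE; break }
      chain <- c(chain, nxt)
    }
    if (ok) chains[[length(chains) + 1]] <- chain
  }
  core <- rep(NA_integer_, length(prot))
  names(core) <- prot
  patterns <- list()
  for (ci in seq_along(chains)) {
    chain <- chains[[ci]]
    in_chain <- rowSums(labels == rep(chain, each = nrow(labels))) == V
    if (sum(in_chain) >= min_core_size) {
      id <- length(patterns) + 1L
      core[in_chain] <- id
      patterns[[id]] <- data.frame(
        core_id = id, t(unname(chain)), size = sum(in_chain))
    }
  }
  pat <- if (length(patterns)) do.call(rbind, patterns) else
    data.frame(core_id = integer(0))
  if (nrow(pat))
    names(pat)[2:(V + 1)] <- paste0("visit", seq_len(V))
  assignment <- data.frame(antibody = prot, labels,
                           core_id = core, row.names = NULL)
  names(assignment)[2:(V + 1)] <- paste0("visit", seq_len(V))
  structure(list(assignment = assignment, patterns = pat,
                 assigned_fraction = mean(!is.na(core)),
                 n_visits = V),
            class = "core_module_assignment")
}

#' @export
print.core_module_assignment <- function(x, ...) {
  cat(sprintf(
    "core_module_assignment: %d core patterns over %d visits; %d/%d proteins assigned (%.0f%%)\n",
    nrow(x$patterns), x$n_visits, sum(!is.na(x$assignment$core_id)),
    nrow(x$assignment), 100 * x$assigned_fraction))
  invisible(x)
}

#' Core-pattern eigengenes per visit
#'
#' First principal component of each core pattern's member proteins,
#' computed per visit at the individual level.
#'
#' @param core a `core_module_assignment`.
#' @param ds the normalized [protein_dataset()] the assignment came from.
#' @return data.frame with `individual_id`, `visit`, one column per core
#'   pattern.
#' @export
core_eigengenes <- function(core, ds) {
  col <- collapse_assays(ds)
  visits <- sort(unique(col$info$visit))
  out <- list()
  for (v in visits) {
    sel <- col$info$visit == v
    expr <- col$values[sel, , drop = FALSE]
    row <- data.frame(individual_id = col$info$individual_id[sel], visit = v)
    for (id in core$patterns$core_id) {
      members <- which(colnames(expr) %in%
                         core$assignment$antibody[!is.na(core$assignment$core_id) &
                                                    core$assignment$core_id == id])
      row[[paste0("core", id)]] <- module_eigengene(expr, members)
    }
    out[[length(out) + 1]] <- row
  }
  do.call(rbind, out)
}

#' Core module-trait association tests
#'
#' Per core pattern, visit and trait: linear regression of the pattern
#' eigengene on a continuous trait, or one-way ANOVA for a categorical
#' trait, with BH-FDR across the whole grid and flags at the configured
#' threshold. The association sign is reported per visit.
#'
#' @param core a `core_module_assignment`.
#' @param ds the normalized [protein_dataset()].
#' @param traits trait data.frame keyed by `individual_id`, `visit`.
#' @param trait_names trait columns to test (default: all non-key columns).
#' @param fdr_threshold default 0.01.
#' @return data.frame with `core_id`, `trait`, `visit`, `estimate`
#'   (slope; NA for ANOVA), `p`, `fdr`, `significant`, `sign`.
#' @export
module_trait_association <- function(core, ds, traits, trait_names = NULL,
                                     fdr_threshold = 0.01) {
  eg <- core_eigengenes(core, ds)
  if (is.null(trait_names))
    trait_names <- setdiff(names(traits), c("individual_id", "visit"))
  key <- paste(eg$individual_id, eg$visit)
  idx <- match(key, paste(traits$individual_id, traits$visit))
  out <- list()
  for (id in core$patterns$core_id) {
    y <- eg[[paste0("core", id)]]
    for (tr in trait_names) {
      tv <- traits[[tr]][idx]
      for (v in unique(eg$visit)) {
        sel <- eg$visit == v & !is.na(tv)
        if (sum(sel) < 3 || length(unique(tv[sel])) < 2) next
        if (is.numeric(tv)) {
          fit <- lm(y[sel] ~ tv[sel])
          s <- summary(fit)$coefficients
          est <- s[2, 1]; p <- s[2, 4]
        } else {
          fit <- aov(y[sel] ~ factor(tv[sel]))
          p <- summary(fit)[[1]][["Pr(>F)"]][1]
          est <- NA_real_
        }
        out[[length(out) + 1]] <- data.frame(
          core_id = id, trait = tr, visit = v, estimate = est, p = p)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame())
  res$fdr <- p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < fdr_threshold
  res$sign <- ifelse(is.na(res$estimate), NA, sign(res$estimate))
  res
}
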