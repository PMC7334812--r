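# exact columns with pairwise correlation 0.5 built from an orthonormal basis
exact_cor_half <- function() {
  e1 <- c(1, -1, 0, 0) / sqrt(2)
  e2 <- c(1, 1, -2, 0) / sqrt(6)
  e3 <- c(1, 1, 1, -3) / sqrt(12)
  x1 <- e1
  x2 <- 0.5 * e1 + sqrt(0.75) * e2
  b <- (0.5 - 0.25) / sqrt(0.75)
  x3 <- 0.5 * e1 + b * e2 + sqrt(1 - 0.25 - b^2) * e3
  m <- cbind(p1 = x1, p2 = x2, p3 = x3)
  stopifnot(max(abs(cor(m) - diag(3) - 0.5 * (1 - diag(3)))) < 1e-12)
  m
}

test_that("topological overlap matches its hand-evaluated closed form", {
  expr <- exact_cor_half()
  at <- adjacency_tom(expr, beta = 1)
  # three proteins all pairwise a = 0.5: omega = (0.25 + 0.5)/(1 + 1 - 0.5)
  off <- at$tom[upper.tri(at$tom)]
  expect_equal(off, rep(0.5, 3), tolerance = 1e-12)
  expect_equal(diag(at$tom), rep(1, 3), ignore_attr = TRUE)
})

test_that("TOM equals a brute-force double loop and stays in [0, 1]", {
  set.seed(41)
  for (i in 1:20) {
    expr <- matrix(rnorm(20 * 15), 20, 15,
                   dimnames = list(NULL, paste0("p", 1:15)))
    beta <- sample(1:6, 1)
    at <- adjacency_tom(expr, beta)
    a <- at$adjacency
    k <- rowSums(a)
    w <- matrix(0, 15, 15)
    for (r in 1:15) for (s in 1:15) {
      if (r == s) { w[r, s] <- 1; next }
      l <- sum(a[r, ] * a[, s])
      w[r, s] <- (l + a[r, s]) / (min(k[r], k[s]) + 1 - a[r, s])
    }
    expect_equal(unname(at$tom), w, tolerance = 1e-12)
    expect_true(all(at$tom >= 0 & at$tom <= 1 + 1e-12))
    expect_equal(at$tom, t(at$tom), tolerance = 1e-12)
  }
})

test_that("adjacency_tom names the offending constant protein", {
  expr <- cbind(a = rnorm(10), b = rep(1, 10), c = rnorm(10))
  expect_error(adjacency_tom(expr, 2), "constant protein: b")
})

test_that("soft power selection handles the degenerate extremes", {
  set.seed(42)
  f <- rnorm(50)
  block <- sapply(1:12, function(i) f)          # perfect 1-block correlation
  colnames(block) <- paste0("p", 1:12)
  expect_equal(as.integer(pick_soft_power(block + 0)), 1L)

  indep <- matrix(rnorm(50 * 30), 50, 30,
                  dimnames = list(NULL, paste0("q", 1:30)))
  expect_warning(b <- pick_soft_power(indep), "best fit")
})

test_that("well-separated planted blocks are recovered exactly", {
  set.seed(43)
  n <- 60
  f <- matrix(rnorm(n * 3), n, 3)
  truth <- rep(1:3, each = 15)
  expr <- sapply(truth, function(m) sqrt(0.8) * f[, m] + sqrt(0.2) * rnorm(n))
  colnames(expr) <- sprintf("p%02d", seq_along(truth))
  at <- adjacency_tom(expr, 2)
  vm <- detect_modules(at$tom, expr)
  expect_equal(length(vm$sizes), 3)
  expect_equal(mclust::adjustedRandIndex(vm$labels, truth), 1)
  # eigengenes are unit variance and positively oriented
  expect_equal(apply(vm$eigengenes, 2, sd), c(M1 = 1, M2 = 1, M3 = 1))
  for (m in 1:3)
    expect_gt(mean(cor(vm$eigengenes[, m], expr[, vm$labels == m])), 0.8)
})

test_that("independent proteins stay almost entirely unassigned", {
  set.seed(44)
  expr <- matrix(rnorm(80 * 50), 80, 50,
                 dimnames = list(NULL, paste0("p", 1:50)))
  at <- adjacency_tom(expr, 2)
  vm <- suppressWarnings(detect_modules(at$tom, expr))
  expect_gte(mean(vm$labels == 0), 0.9)
})

test_that("module labels are equivariant under protein permutation", {
  set.seed(45)
  n <- 50
  f <- matrix(rnorm(n * 2), n, 2)
  truth <- rep(1:2, each = 12)
  expr <- sapply(truth, function(m) sqrt(0.8) * f[, m] + sqrt(0.2) * rnorm(n))
  colnames(expr) <- sprintf("p%02d", seq_along(truth))
  perm <- sample(ncol(expr))
  vm1 <- detect_modules(adjacency_tom(expr, 2)$tom, expr)
  vm2 <- detect_modules(adjacency_tom(expr[, perm], 2)$tom, expr[, perm])
  expect_equal(mclust::adjustedRandIndex(vm1$labels[perm], vm2$labels), 1)
})

make_vm <- function(labels, visit) {
  structure(list(labels = labels, eigengenes = NULL,
                 sizes = table(labels[labels > 0]), visit = visit),
            class = "visit_modules")
}

test_that("identical per-visit labels yield core patterns equal to the modules", {
  labels <- setNames(rep(c(1L, 2L, 0L), times = c(8, 8, 4)),
                     sprintf("p%02d", 1:20))
  core <- match_core_modules(list(make_vm(labels, 1), make_vm(labels, 2),
                                  make_vm(labels, 3)))
  expect_equal(nrow(core$patterns), 2)
  expect_equal(core$assigned_fraction, mean(labels > 0))
  expect_true(all(core$assignment$core_id[labels > 0] ==
                    labels[labels > 0]))
})

test_that("core matching does not depend on module numbering", {
  labels <- setNames(rep(c(1L, 2L, 3L, 0L), times = c(7, 7, 6, 5)),
                     sprintf("p%02d", 1:25))
  relab <- labels
  relab[labels == 1L] <- 3L; relab[labels == 2L] <- 1L
  relab[labels == 3L] <- 2L
  a <- match_core_modules(list(make_vm(labels, 1), make_vm(labels, 2)))
  b <- match_core_modules(list(make_vm(labels, 1), make_vm(relab, 2)))
  expect_equal(a$assigned_fraction, b$assigned_fraction)
  expect_identical(is.na(a$assignment$core_id), is.na(b$assignment$core_id))
})

test_that("scrambling one visit collapses core assignment towards chance", {
  set.seed(46)
  labels <- setNames(sample(rep(c(1L, 2L, 3L, 4L), each = 15)),
                     sprintf("p%02d", 1:60))
  perm_labels <- setNames(sample(labels), names(labels))
  intact <- match_core_modules(list(make_vm(labels, 1), make_vm(labels, 2),
                                    make_vm(labels, 3)))
  broken <- match_core_modules(list(make_vm(labels, 1),
                                    make_vm(perm_labels, 2),
                                    make_vm(labels, 3)))
  expect_equal(intact$assigned_fraction, 1)
  # greedy matching keeps only the best-overlapping chance pairs, so the
  # surviving fraction sits well below the intact assignment
  expect_lt(broken$assigned_fraction, 0.6)
})

test_that("core eigengene-trait links are detected with their signs", {
  co <- cached("module_cohort", function() {
    cfg <- small_config(n_individuals = 50L, frac_module = 0.8,
                        frac_unstable = 0.2, n_seasonal = 0L,
                        n_deviant_baseline = 0L, n_deviant_trend = 0L,
                        n_deviant_spike = 0L, n_cis_effects = 0L,
                        n_snps = 50L)
    out <- simulate_cohort(cfg)
    out$normalized <- suppressWarnings(normalize_pipeline(out$dataset))$dataset
    out
  })
  vm <- suppressWarnings(modules_per_visit(co$normalized))
  core <- match_core_modules(vm)
  expect_gte(nrow(core$patterns), 1)
  eg <- core_eigengenes(core, co$normalized)
  tr <- data.frame(individual_id = eg$individual_id, visit = eg$visit)
  set.seed(47)
  id <- core$patterns$core_id[1]
  tr$linked <- eg[[paste0("core", id)]] + rnorm(nrow(eg), sd = 0.2)
  tr$anti <- -eg[[paste0("core", id)]] + rnorm(nrow(eg), sd = 0.2)
  tr$null <- rnorm(nrow(eg))
  res <- module_trait_association(core, co$normalized, tr,
                                  trait_names = c("linked", "anti", "null"))
  hit <- subset(res, core_id == id & trait == "linked")
  expect_true(all(hit$significant))
  expect_true(all(hit$sign == 1))
  anti <- subset(res, core_id == id & trait == "anti")
  expect_true(all(anti$sign == -1))
  null_rows <- subset(res, trait == "null")
  expect_lt(mean(null_rows$significant), 0.2)
})
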