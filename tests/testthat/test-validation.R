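test_that("varimax loadings reproduce the correlation matrix", {
  set.seed(20)
  n <- 300
  f <- matrix(rnorm(2 * n), n)
  x <- cbind(f %*% c(1, 0.2), f %*% c(0.9, 0.3), f %*% c(0.1, 1), f %*% c(0.2, 0.8)) +
    matrix(rnorm(4 * n, sd = 0.4), n)
  A <- varimax_loadings(x)
  R <- cor(x)
  expect_equal(unclass(A) %*% t(unclass(A)), R, tolerance = 1e-8,
               ignore_attr = TRUE)
  # varimax criterion does not decrease relative to the unrotated loadings
  crit <- function(L) sum(apply(L^2, 2, var))
  e <- eigen(R, symmetric = TRUE)
  L0 <- e$vectors %*% diag(sqrt(e$values))
  expect_gte(crit(unclass(A)), crit(L0) - 1e-10)
  # uncorrelated variables: loadings are identity up to sign/permutation
  set.seed(21)
  xi <- matrix(rnorm(4 * 20000), ncol = 4)
  Ai <- abs(unclass(varimax_loadings(xi)))
  expect_equal(sort(apply(Ai, 1, max)), rep(1, 4), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_lt(sum(Ai > 0.5), 5)
})

test_that("loading matrix round-trips through the plain-text handoff file", {
  set.seed(22)
  A <- varimax_loadings(matrix(rnorm(400), 100, 4))
  path <- tempfile(fileext = ".txt")
  write_loadings(A, path)
  B <- read_loadings(path)
  expect_equal(unclass(B), unclass(A), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("simulated null data match the target correlations and are seeded", {
  set.seed(23)
  x <- matrix(rnorm(500 * 3), 500)
  x[, 2] <- 0.7 * x[, 1] + sqrt(1 - 0.49) * x[, 2]
  A <- varimax_loadings(x)
  big <- simulate_null(A, 50000, seed = 7)
  expect_lt(max(abs(cor(big) - attr(A, "R"))), 0.02)
  expect_true(all(abs(colMeans(big)) < 1e-10))
  expect_identical(simulate_null(A, 100, seed = 9), simulate_null(A, 100, seed = 9))
  # identity loadings give independent standard normals
  I4 <- structure(diag(4), class = c("loading_matrix", "matrix"))
  z <- simulate_null(I4, 20000, seed = 3)
  off <- cor(z); diag(off) <- 0
  expect_lt(max(abs(off)), 0.03)
})

test_that("MORI is 0 at the null mean, near 0 under self-null data, reproducible", {
  # observed QCs equal to null means -> all MORI = 0 by construction
  set.seed(24)
  x <- matrix(rnorm(400), 100, 4)
  A <- varimax_loadings(x)
  obs <- simulate_null(A, 200, seed = 100)  # a draw from the null itself
  clus <- function(d) kcenter(d, 3, n_starts = 5, seed = 42)$labels
  rep1 <- mori(obs, clus, reps = 25, seed = 55)
  rep2 <- mori(obs, clus, reps = 25, seed = 55)
  expect_identical(rep1$table, rep2$table)  # bit-reproducible
  expect_true(all(abs(rep1$table$mori) <= 0.1, na.rm = TRUE))
  expect_true(all(is.finite(rep1$table$null_sd)))
})

test_that("planted strong structure yields large MORI for EESS%", {
  gt <- strong_typology(n = 500, seed = 26)
  z <- standardize(gt$data)
  clus <- function(d) kcenter(d, 7, n_starts = 5, seed = 3)$labels
  rep <- mori(z, clus, reps = 10, seed = 8, silhouette = FALSE)
  expect_gt(rep$table$mori[rep$table$qc == "EESS_pct"], 0.5)
})

test_that("centroid matching is exact, symmetric and beats naive pairing", {
  set.seed(27)
  ca <- matrix(rnorm(12), 4, 3)
  perm <- c(3, 1, 4, 2)
  cm <- centroid_match(ca, ca[perm, ])
  expect_equal(max(cm$pairs$ased), 0, tolerance = 1e-12)
  expect_equal(cm$pairs$cluster_b[order(cm$pairs$cluster_a)], order(perm))
  # symmetry: A->B and B->A give the same pair set and total
  cb <- matrix(rnorm(12), 4, 3)
  ab <- centroid_match(ca, cb); ba <- centroid_match(cb, ca)
  expect_equal(ab$total, ba$total, tolerance = 1e-12)
  pairs_ab <- with(ab$pairs, sort(paste(cluster_a, cluster_b)))
  pairs_ba <- with(ba$pairs, sort(paste(cluster_b, cluster_a)))
  expect_identical(pairs_ab, pairs_ba)
  # assignment total never exceeds identity pairing
  for (seed in 1:5) {
    set.seed(seed)
    u <- matrix(rnorm(15), 5, 3); v <- matrix(rnorm(15), 5, 3)
    ident <- sum(sapply(1:5, function(i) sum((u[i, ] - v[i, ])^2) / 3))
    expect_lte(centroid_match(u, v)$total, ident + 1e-12)
  }
})

test_that("CMR follows the harmonic-mean formula and marginals are conserved", {
  labs <- rep(1:3, times = c(30, 40, 30))
  xc <- exacon_cmr(labs, labs)
  expect_equal(unname(diag(xc$cmr)), rep(1, 3))
  expect_equal(xc$cmr[upper.tri(xc$cmr)], rep(0, 3))
  # cell 40 with marginals 50 and 50 -> 0.8
  a <- rep(1:2, each = 50)
  b <- c(rep(1, 40), rep(2, 10), rep(2, 40), rep(1, 10))
  xc2 <- exacon_cmr(a, b)
  expect_equal(xc2$cmr[1, 1], 0.8)
  expect_equal(rowSums(xc2$table), c(50, 50), ignore_attr = TRUE)
  expect_equal(colSums(xc2$table), c(50, 50), ignore_attr = TRUE)
  # relabeling leaves the matched CMR multiset unchanged
  set.seed(28)
  p <- sample(1:4, 120, TRUE); q <- sample(1:4, 120, TRUE)
  c1 <- exacon_cmr(p, q)$cmr
  relab <- c(2, 4, 1, 3)
  c2 <- exacon_cmr(relab[p], q)$cmr
  expect_equal(sort(as.vector(c1)), sort(as.vector(c2)), tolerance = 1e-12)
})

test_that("match_solutions ties centroid pairs to their CMRs", {
  gt <- strong_typology(n = 350, seed = 29)
  z <- standardize(gt$data)
  fit <- kcenter(z, 7, n_starts = 20, seed = 4)
  m <- match_solutions(z, fit$labels, gt$labels)
  expect_equal(nrow(m), 7L)
  expect_true(all(diff(m$ased) >= 0))
  expect_gt(mean(m$cmr), 0.95)
  expect_true(all(m$cmr >= 0 & m$cmr <= 1))
})
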