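test_that("HC matches the brute-force pairwise ASED mean and its identities", {
  set.seed(12)
  x <- standardize(matrix(rnorm(160), 40))
  labs <- sample(1:4, 40, replace = TRUE)
  labs <- as_partition(labs)$labels
  res <- cluster_hc(x, labs)
  expect_equal(res$hc, brute_hc(x, labs), tolerance = 1e-10)
  expect_equal(res$hc_mean, sum(res$sizes * res$hc) / 40)
  # identical points -> HC 0
  y <- rbind(matrix(1, 5, 3), matrix(0, 5, 3))
  expect_equal(cluster_hc(y, rep(1:2, each = 5))$hc, c(0, 0))
  # the whole standardized sample as one cluster has HC exactly 2
  expect_equal(cluster_hc(x, rep(1, 40))$hc, 2, tolerance = 1e-10)
  # sum_c (n_c - 1) HC_c p / 2 = TotalWSS
  expect_equal(sum((res$sizes - 1) * res$hc * ncol(x) / 2),
               wss_series(x, list(labs))$total_wss, tolerance = 1e-9)
})

test_that("EESS% extremes and the per-variable eta-squared aggregation agree", {
  set.seed(14)
  x <- standardize(matrix(rnorm(120), 30))
  expect_equal(eess_pct(x, 1:30), 100)
  expect_equal(eess_pct(x, rep(1, 30)), 0)
  labs <- as_partition(sample(1:3, 30, TRUE))$labels
  # independent route: pooled between-group SS over all variables via anova
  ss <- sapply(seq_len(ncol(x)), function(j) {
    a <- anova(lm(x[, j] ~ factor(labs)))
    c(between = a$`Sum Sq`[1], total = sum(a$`Sum Sq`))
  })
  expect_equal(eess_pct(x, labs), 100 * sum(ss["between", ]) / sum(ss["total", ]),
               tolerance = 1e-9)
})

test_that("XBmod degenerate cases and monotonicity in separation", {
  # two clusters at identical centroids: XBmod = -HCmean < 0
  set.seed(15)
  x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40), 20))
  labs <- rep(1:2, each = 20)
  xc <- x
  xc[labs == 2, ] <- xc[labs == 2, ] - matrix(colMeans(xc[labs == 2, , drop = FALSE]) -
    colMeans(xc[labs == 1, , drop = FALSE]), 20, 2, byrow = TRUE)
  expect_equal(xbmod(xc, labs), -cluster_hc(xc, labs)$hc_mean, tolerance = 1e-9)
  # two point-clusters at ASED d: XBmod = d
  y <- rbind(matrix(0, 4, 2), matrix(3, 4, 2))
  expect_equal(xbmod(y, rep(1:2, each = 4)), 9)
  # increasing separation strictly increases XBmod at fixed spread
  set.seed(16)
  base <- matrix(rnorm(60, sd = 0.4), 30)
  vals <- sapply(c(1, 2, 4, 8), function(sep) {
    xx <- base; xx[16:30, ] <- xx[16:30, ] + sep
    xbmod(xx, rep(1:2, each = 15))
  })
  expect_true(all(diff(vals) > 0))
})

test_that("mean silhouette matches the O(n^2) reference", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(50), 25)
    labs <- as_partition(sample(1:3, 25, TRUE))$labels
    d <- pairwise_distances(x, "euclidean")
    expect_equal(silhouette_mean(d, labs), brute_silhouette_mean(d, labs),
                 tolerance = 1e-12)
  }
  b <- two_blobs(n_per = 20, sep = 10, sd = 0.3, seed = 4)
  expect_gt(silhouette_mean(b$x, b$labels), 0.8)
  # a = 0, b > 0 gives s = 1
  z <- rbind(matrix(0, 5, 2), matrix(4, 5, 2))
  expect_equal(silhouette_mean(z, rep(1:2, each = 5)), 1)
})

test_that("homogeneity percentages reproduce the published worked examples", {
  # 7-cluster hierarchical solution: printed sizes and HCs
  hc4 <- c(0.55, 1.01, 0.18, 0.73, 0.20, 0.76, 0.81)
  sz4 <- c(55, 88, 161, 132, 228, 88, 41)
  hom <- homogeneity_percentages(hc4, sz4)
  expect_equal(round(hom[["Hom30"]], 1), 49.1)
  expect_equal(round(hom[["Hom50"]], 1), 49.1)
  expect_equal(round(hom[["Hom20"]], 1), 20.3)
  expect_equal(hom[["Hom10"]], 0)
  # 7-cluster k-means solution
  hc8 <- c(0.51, 0.24, 0.20, 0.52, 0.84, 0.70, 0.94)
  sz8 <- c(101, 211, 205, 80, 51, 71, 74)
  expect_equal(round(homogeneity_percentages(hc8, sz8)[["Hom30"]], 1), 52.5)
  # 10-cluster mixture solution: 39% of cases in clusters with HC < 0.10.
  # Only 9 cluster rows are printed (742 of 793 cases); the remaining
  # 51-case cluster is not among the four HC < 0.10 ones, so its HC is
  # represented by any value >= 0.10.
  hc12 <- c(1.15, 0.95, 0.74, 0.01, 0.05, 1.09, 0.75, 0.03, 0.08, 1)
  sz12 <- c(94, 45, 78, 58, 68, 133, 83, 68, 115, 51)
  expect_equal(round(homogeneity_percentages(hc12, sz12)[["Hom10"]]), 39)
  # monotone in threshold; all-heterogeneous gives zeros
  expect_true(all(diff(hom) >= 0))
  expect_equal(unname(homogeneity_percentages(c(0.5, 0.9), c(10, 10))),
               c(0, 0, 0, 0))
})

test_that("acceptability applies the strict QC thresholds", {
  ok <- list(EESS_pct = 78.5, XBmod = 0.554, HCmean = 0.435)
  expect_true(acceptability(ok)[["acceptable"]])
  bad <- list(EESS_pct = 44.4, XBmod = -0.948, HCmean = 1.122)
  fl <- acceptability(bad)
  expect_false(fl[["acceptable"]])
  expect_false(fl[["eess"]]); expect_false(fl[["xbmod"]]); expect_false(fl[["hcmean"]])
  # boundary equality fails under strict ">"
  expect_false(acceptability(list(EESS_pct = 70, XBmod = 0.554, HCmean = 0.435))[["eess"]])
})

test_that("pattern codes follow the z-bands and survive relabeling", {
  expect_equal(clustype:::pattern_code(0.05), ".")
  expect_equal(clustype:::pattern_code(-0.3), "(L)")
  expect_equal(clustype:::pattern_code(0.42), "(H)")
  expect_equal(clustype:::pattern_code(-0.7), "L")
  expect_equal(clustype:::pattern_code(-1.2), "L+")
  expect_equal(clustype:::pattern_code(1.7), "H++")
  expect_equal(clustype:::pattern_code(-2.2), "L+++")
  expect_equal(clustype:::pattern_code(2.7), "H++++")
  set.seed(18)
  x <- standardize(matrix(rnorm(200), 50))
  labs <- as_partition(sample(1:3, 50, TRUE))$labels
  pt <- pattern_table(x, labs)
  expect_equal(nrow(pt), 3L)
  expect_equal(sum(pt$CLsize), 50)
  # QCs are invariant to cluster relabeling and case order
  perm <- sample(50)
  q1 <- qc_set(x, labs); q2 <- qc_set(x[perm, ], labs[perm])
  expect_equal(q1$EESS_pct, q2$EESS_pct)
  expect_equal(q1$HCmean, q2$HCmean)
  expect_equal(q1$XBmod, q2$XBmod)
  relab <- c(3, 1, 2)[labs]
  q3 <- qc_set(x, relab)
  expect_equal(q1$Hom50, q3$Hom50)
  expect_equal(q1$HCmean, q3$HCmean)
})

test_that("EESS% and HCmean satisfy the approximate complementarity relation", {
  gt <- generate_typology(typology_spec(n = 800), seed = 31)
  z <- standardize(gt$data)
  fit <- kcenter(z, 7, seed = 2)
  expect_true(all(fit$sizes >= 20))
  q <- qc_set(z, fit$labels, silhouette = FALSE)
  expect_lt(abs(q$EESS_pct - 100 * (1 - q$HCmean / 2)), 1.5)
})
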