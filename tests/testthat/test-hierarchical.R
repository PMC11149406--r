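test_that("single linkage on a line merges nearest points first", {
  x <- cbind(c(0, 1, 10))
  d <- ahca(x, method = "single", spec = "euclidean")
  expect_equal(d$height, c(1, 9))
  expect_equal(cut_tree(d, 2), c(1, 1, 2))
})

test_that("single-linkage merge heights equal sorted MST edge weights", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(40), 20)
    dm <- pairwise_distances(x, "euclidean")
    dend <- ahca(x, method = "single", spec = "euclidean")
    expect_equal(sort(dend$height), prim_mst_weights(dm), tolerance = 1e-10)
  }
})

test_that("ward separates far blobs with a dominant final merge", {
  b <- two_blobs(n_per = 15, sep = 10, seed = 3)
  dend <- ahca(b$x, method = "ward", spec = "squared_euclidean")
  h <- dend$height
  expect_gt(h[length(h)], 10 * max(h[-length(h)]))
  expect_equal(cut_tree(dend, 2), b$labels)
})

test_that("all eight linkages produce valid dendrograms", {
  set.seed(8)
  x <- matrix(rnorm(48), 12)
  for (m in c("average", "single", "complete", "centroid", "median", "ward",
              "flexible_beta", "mcquitty")) {
    dend <- ahca(x, method = m)
    expect_s3_class(dend, "dendro")
    expect_equal(nrow(dend$merge), 11L)
    expect_true(all(dend$height >= 0))
    if (!m %in% c("centroid", "median")) {
      expect_true(all(diff(dend$height) >= -1e-10))
    }
    expect_equal(sort(unique(cut_tree(dend, 3))), 1:3)
  }
})

test_that("diana reproduces the splinter rule and diameter heights", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(8:15, 1)
    x <- matrix(rnorm(n * 3), n)
    dm <- pairwise_distances(x, "euclidean")
    dend <- dhca(x, spec = "euclidean")
    nodes <- node_leaf_sets(dend$merge)
    for (i in seq_along(nodes)) {
      members <- sort(c(nodes[[i]][[1]], nodes[[i]][[2]]))
      # split height equals the diameter of the divided cluster
      expect_equal(dend$height[i], max(dm[members, members]), tolerance = 1e-10)
      # the two children are exactly the splinter-procedure split
      sp <- splinter_split(dm, members)
      got <- list(nodes[[i]][[1]], nodes[[i]][[2]])
      expect_true(setequal_pair(sp, got))
    }
  }
})

test_that("diana separates well-separated pairs first and handles n = 2", {
  x <- cbind(c(0, 0.1, 10, 10.1))
  dend <- dhca(x, spec = "euclidean")
  expect_equal(cut_tree(dend, 2), c(1, 1, 2, 2))
  d2 <- dhca(cbind(c(0, 3)), spec = "euclidean")
  expect_equal(d2$height, 3)
})

test_that("cut_tree obeys the horizontal-line rule on a chain tree", {
  x <- cbind(c(0, 1, 3, 7, 15))  # chain: each merge height doubles
  dend <- ahca(x, method = "single", spec = "euclidean")
  expect_equal(cut_tree(dend, nrow(x)), 1:5)
  expect_equal(cut_tree(dend, 1), rep(1, 5))
  for (k in 2:4) {
    labs <- cut_tree(dend, k)
    expect_equal(max(labs), k)
  }
  expect_error(cut_tree(dend, 0), "range")
  expect_error(cut_tree(dend, 6), "range")
})

test_that("nested cuts split exactly one cluster at a time", {
  set.seed(13)
  x <- matrix(rnorm(60), 20)
  dend <- ahca(x)
  for (k in 2:8) {
    a <- cut_tree(dend, k); b <- cut_tree(dend, k + 1)
    # every k+1 cluster sits inside one k cluster; exactly one k cluster splits
    tab <- table(a, b)
    expect_true(all(colSums(tab > 0) == 1))
    expect_equal(sum(rowSums(tab > 0) == 2), 1L)
  }
})

test_that("case-order permutation changes labels only", {
  set.seed(21)
  x <- matrix(rnorm(72), 24)
  dend <- ahca(x)
  labs <- cut_tree(dend, 4)
  perm <- sample(nrow(x))
  labs_p <- cut_tree(ahca(x[perm, ]), 4)
  # same partition after mapping back through the permutation
  expect_equal(canon <- as_partition(labs[perm])$labels,
               as_partition(labs_p)$labels)
})

test_that("wss series is exact at the extremes and matches the pairwise identity", {
  set.seed(6)
  x <- matrix(rnorm(45), 15)
  dend <- ahca(x)
  ws <- wss_series(x, dend, k_range = c(1, 4, 15))
  tss <- sum(sweep(x, 2, colMeans(x), "-")^2)
  expect_equal(ws$total_wss[ws$k == 1], tss)
  expect_equal(ws$total_wss[ws$k == 15], 0)
  expect_true(all(diff(wss_series(x, dend, k_range = 1:15)$total_wss) <= 1e-10))
  # WSS_c = (sum of pairwise squared distances within c) / n_c
  labs <- cut_tree(dend, 4)
  d2 <- pairwise_distances(x, "squared_euclidean")
  alt <- sum(vapply(1:4, function(c) {
    idx <- which(labs == c)
    sum(d2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
  expect_equal(ws$total_wss[ws$k == 4], alt, tolerance = 1e-9)
})

test_that("merge table export round-trips sizes and heights", {
  set.seed(2)
  x <- matrix(rnorm(30), 10)
  dend <- ahca(x)
  path <- tempfile(fileext = ".tsv")
  tab <- export_merge_table(dend, path)
  back <- read.delim(path)
  expect_equal(back$height, dend$height)
  expect_equal(back$size[nrow(back)], 10L)
})
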