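# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities from first principles (double loops, enumeration,
# grids) so they share no code with the implementation paths they check.

# mean pairwise ASED within each cluster, by explicit double loop
brute_hc <- function(x, labels) {
  vapply(sort(unique(labels)), function(c) {
    idx <- which(labels == c)
    if (length(idx) < 2L) return(0)
    tot <- 0; np <- 0
    for (i in idx) for (j in idx) if (i < j) {
      tot <- tot + sum((x[i, ] - x[j, ])^2) / ncol(x)
      np <- np + 1
    }
    tot / np
  }, numeric(1L))
}

# Rousseeuw silhouette by explicit loops
brute_silhouette_mean <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- table(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[[as.character(ci)]] == 1L) { s[i] <- 0; next }
    a <- mean(d[i, labels == ci & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), ci),
                    function(c) mean(d[i, labels == c]), numeric(1L)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# minimum spanning tree edge weights by Prim's algorithm
prim_mst_weights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  w <- numeric(0)
  while (sum(in_tree) < n) {
    sub <- d[in_tree, !in_tree, drop = FALSE]
    w <- c(w, min(sub))
    j <- which(!in_tree)[which(sub == min(sub), arr.ind = TRUE)[1L, 2L]]
    in_tree[j] <- TRUE
  }
  sort(w)
}

# Kaufman-Rousseeuw splinter split of the index set idx under distances d
splinter_split <- function(d, idx) {
  d <- as.matrix(d)
  if (length(idx) == 2L) return(list(sort(idx[1L]), sort(idx[2L])))
  avg <- vapply(idx, function(i) mean(d[i, setdiff(idx, i)]), numeric(1L))
  S <- idx[which.max(avg)]
  R <- setdiff(idx, S)
  repeat {
    if (length(R) == 1L) break
    gain <- vapply(R, function(i) {
      mean(d[i, setdiff(R, i)]) - mean(d[i, S])
    }, numeric(1L))
    if (max(gain) <= 0) break
    mv <- R[which.max(gain)]
    S <- c(S, mv); R <- setdiff(R, mv)
  }
  list(sort(S), sort(R))
}

# unordered equality of two two-set splits
setequal_pair <- function(a, b) {
  (identical(a[[1]], b[[1]]) && identical(a[[2]], b[[2]])) ||
    (identical(a[[1]], b[[2]]) && identical(a[[2]], b[[1]]))
}

# leaf sets of the two children of every internal node of a merge table
node_leaf_sets <- function(merge) {
  n <- nrow(merge) + 1L
  leaves <- vector("list", nrow(merge))
  get <- function(ch) if (ch < 0) -ch else leaves[[ch]]
  out <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    a <- get(merge[i, 1L]); b <- get(merge[i, 2L])
    leaves[[i]] <- sort(c(a, b))
    out[[i]] <- list(sort(a), sort(b))
  }
  out
}

# exhaustive minimum total WSS over all 2-partitions (n <= ~15)
exhaustive_kmeans2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1L) - 1L)) {
    lab <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(lab)) < 2L) next
    wss <- sum(vapply(1:2, function(c) {
      xc <- x[lab == c, , drop = FALSE]
      sum(sweep(xc, 2L, colMeans(xc), "-")^2)
    }, numeric(1L)))
    best <- min(best, wss)
  }
  best
}

# exhaustive PAM objective over all medoid sets of size k
exhaustive_pam <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  sets <- utils::combn(nrow(x), k)
  min(apply(sets, 2L, function(m) sum(apply(d[, m, drop = FALSE], 1L, min))))
}

# two-stage grid minimizer of the sum of Euclidean distances
grid_geometric_median <- function(x, step = 1e-4) {
  obj <- function(gx, gy) {
    g <- cbind(rep(gx, each = length(gy)), rep(gy, length(gx)))
    o <- rowSums(sqrt(outer(g[, 1], x[, 1], "-")^2 + outer(g[, 2], x[, 2], "-")^2))
    g[which.min(o), ]
  }
  lo <- apply(x, 2L, min) - 0.5; hi <- apply(x, 2L, max) + 0.5
  ctr <- obj(seq(lo[1], hi[1], by = 0.02), seq(lo[2], hi[2], by = 0.02))
  ctr <- obj(seq(ctr[1] - 0.03, ctr[1] + 0.03, by = 1e-3),
             seq(ctr[2] - 0.03, ctr[2] + 0.03, by = 1e-3))
  obj(seq(ctr[1] - 0.002, ctr[1] + 0.002, by = step),
      seq(ctr[2] - 0.002, ctr[2] + 0.002, by = step))
}

# two well-separated Gaussian blobs
two_blobs <- function(n_per = 20L, sep = 8, p = 2L, sd = 0.5, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * p, 0, sd), n_per),
             matrix(stats::rnorm(n_per * p, sep, sd), n_per))
  list(x = x, labels = rep(1:2, each = n_per))
}

# strongly separated 7-blob typology (sharper than the study-like default)
strong_typology <- function(n = 700L, seed = 1L) {
  cents <- 3 * rbind(c(1, 1, 1, 1), c(-1, -1, -1, -1), c(1, -1, 1, -1),
                     c(-1, 1, -1, 1), c(1, 1, -1, -1), c(-1, -1, 1, 1),
                     c(0, 0, 0, 0))
  generate_typology(typology_spec(n = n, centroids = cents,
                                  proportions = rep(1 / 7, 7), sd = 0.3),
                    seed = seed)
}
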