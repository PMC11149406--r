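#' Varimax-rotated full principal-component loading matrix
#'
#' Extracts all p principal components of the correlation matrix of the
#' input variables (loadings = eigenvectors scaled by sqrt eigenvalues) and
#' applies a varimax rotation with Kaiser row-normalization.  Because the
#' rotation is orthogonal and all components are retained, A A' reproduces
#' the correlation matrix exactly; this is the handoff file the simulation
#' null consumes.
#'
#' @param x numeric data matrix with p >= 2 columns.
#' @return p x p loading matrix (class \code{"loading_matrix"}) with the
#'   correlation matrix in attribute \code{"R"}.
#' @export
varimax_loadings <- function(x) {
  x <- as_data_matrix(x)
  p <- ncol(x)
  if (p < 2L) stop("need p >= 2")
  R <- stats::cor(x)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 1e-10) stop("correlation matrix is rank-deficient")
  L <- e$vectors %*% diag(sqrt(e$values), p)
  A <- unclass(stats::varimax(L, normalize = TRUE)$loadings)
  dimnames(A) <- list(colnames(x), paste0("PC", seq_len(p)))
  structure(A, class = c("loading_matrix", "matrix"), R = R)
}

#' Read/write a plain-text loading matrix
#'
#' Round-trips the p x p loading matrix through a whitespace-separated text
#' file, the hand-off format between the PCA step and the validation step.
#'
#' @param A loading matrix (write) / path (read).
#' @param path file path.
#' @export
write_loadings <- function(A, path) {
  utils::write.table(unclass(A), path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_loadings
#' @export
read_loadings <- function(path) {
  A <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(A) <- NULL
  if (nrow(A) != ncol(A)) stop("loading matrix must be square (all components retained)")
  structure(A, class = c("loading_matrix", "matrix"), R = A %*% t(A))
}

#' Simulate correlation-matched multivariate-normal null data
#'
#' Draws n cases as x = A z with z iid standard normal, so the population
#' correlations match those of the observed variables, then re-standardizes
#' every column (the null replicates are clustered on z-scores exactly like
#' the observed data).
#'
#' @param loadings a \code{\link{varimax_loadings}} matrix (or any p x p A).
#' @param n number of cases.
#' @param seed RNG seed.
#' @return standardized n x p matrix.
#' @export
simulate_null <- function(loadings, n, seed = NULL) {
  A <- unclass(loadings)
  p <- nrow(A)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * p), n, p)
  x <- z %*% t(A)
  colnames(x) <- rownames(A)
  standardize(x)
}

#' MORI relative-improvement coefficients
#'
#' Measures how much better the observed cluster solution's quality
#' coefficients are than those of identical clusterings of simulated random
#' data: \code{reps} replicates are drawn from the correlation-matched normal
#' null (\code{\link{simulate_null}}), clustered with the same configuration,
#' and each QC's null mean rbar is compared with the observed value on the
#' scale of the remaining headroom towards its ideal value: \cr
#' EESS\%: (obs - rbar)/(100 - rbar); silhouette: (obs - rbar)/(1 - rbar);
#' HCmean: (rbar - obs)/rbar; XBmod: (obs - rbar)/(2 - rbar), 2 being the
#' expected ASED of independent standardized cases.  0 means no improvement
#' over random structure, 1 means the ideal value was reached; a QC whose
#' null mean already sits at the ideal value is undefined (NA).
#'
#' @param x observed standardized data matrix.
#' @param clusterer function(data) -> integer labels reproducing the observed
#'   pipeline (same algorithm, k, seeding policy).
#' @param labels optional observed labels; defaults to \code{clusterer(x)}.
#' @param reps independent simulation repetitions (default 25).
#' @param seed master seed; per-replicate seeds are spawned from it.
#' @param silhouette include the silhouette QC (default TRUE).
#' @return object of class \code{"mori_report"}: data.frame with observed,
#'   null_mean, null_sd, mori per QC, plus reps and seed.
#' @export
mori <- function(x, clusterer, labels = NULL, reps = 25L, seed = 1L,
                 silhouette = TRUE) {
  x <- as_data_matrix(x)
  if (reps < 2L) stop("reps must be >= 2")
  if (is.null(labels)) labels <- clusterer(x)
  obs <- qc_vector(x, labels, silhouette)
  A <- varimax_loadings(x)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  null_qc <- t(vapply(seq_len(reps), function(r) {
    xs <- simulate_null(A, nrow(x), seed = rep_seeds[r])
    qc_vector(xs, clusterer(xs), silhouette)
  }, obs))
  rbar <- colMeans(null_qc)
  rsd <- apply(null_qc, 2L, stats::sd)
  ideal <- c(EESS_pct = 100, XBmod = 2, HCmean = 0, mean_silhouette = 1)[names(obs)]
  denom <- ifelse(names(obs) == "HCmean", rbar, ideal - rbar)
  mori <- ifelse(abs(denom) < 1e-12, NA_real_,
                 ifelse(names(obs) == "HCmean", (rbar - obs) / denom,
                        (obs - rbar) / denom))
  structure(list(table = data.frame(qc = names(obs), observed = unname(obs),
                                    null_mean = unname(rbar), null_sd = unname(rsd),
                                    mori = unname(mori), stringsAsFactors = FALSE),
                 reps = reps, seed = seed),
            class = "mori_report")
}

qc_vector <- function(x, labels, silhouette) {
  q <- qc_set(x, labels, silhouette = silhouette)
  v <- c(EESS_pct = q$EESS_pct, XBmod = q$XBmod, HCmean = q$HCmean)
  if (silhouette) v <- c(v, mean_silhouette = q$mean_silhouette)
  v
}

#' @export
print.mori_report <- function(x, ...) {
  cat(sprintf("MORI report (%d simulation replicates, seed %d)\n", x$reps, x$seed))
  print(transform(x$table, observed = round(observed, 3),
                  null_mean = round(null_mean, 3), null_sd = round(null_sd, 3),
                  mori = round(mori, 3)), row.names = FALSE)
  invisible(x)
}

# exact minimum-cost assignment via bitmask dynamic programming (k <= 20)
min_cost_assignment <- function(cost) {
  k <- nrow(cost)
  stopifnot(ncol(cost) == k)
  if (k > 20L) stop("assignment DP supports up to k = 20")
  full <- bitwShiftL(1L, k)
  dp <- rep(Inf, full); dp[1L] <- 0
  choice <- matrix(NA_integer_, full, 1L)
  from <- integer(full)
  for (mask in 0:(full - 1L)) {
    if (!is.finite(dp[mask + 1L])) next
    i <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) > 0L)  # rows assigned
    if (i == k) next
    for (j in 0:(k - 1L)) {
      if (bitwAnd(mask, bitwShiftL(1L, j)) > 0L) next
      nm <- bitwOr(mask, bitwShiftL(1L, j))
      val <- dp[mask + 1L] + cost[i + 1L, j + 1L]
      if (val < dp[nm + 1L]) {
        dp[nm + 1L] <- val
        choice[nm + 1L, 1L] <- j + 1L
        from[nm + 1L] <- mask
      }
    }
  }
  assign <- integer(k)
  mask <- full - 1L
  for (i in k:1) {
    j <- choice[mask + 1L, 1L]
    assign[i] <- j
    mask <- from[mask + 1L]
  }
  list(assignment = assign, total = dp[full])
}

#' Match cluster centroids between two solutions
#'
#' Computes the full k_a x k_b ASED matrix between the centroids of two
#' cluster solutions on the same variables and, when k_a = k_b, the
#' one-to-one pairing minimizing the total ASED (exact assignment).  The
#' matched distances are reported in increasing order.
#'
#' @param centroids_a,centroids_b k x p centroid matrices, or
#'   \code{"kcenter_fit"} objects (their \code{centers} are used).
#' @return list: \code{ased} (k_a x k_b matrix), \code{pairs} (data.frame
#'   cluster_a, cluster_b, ased, sorted increasing), \code{total}.
#' @export
centroid_match <- function(centroids_a, centroids_b) {
  ca <- extract_centers(centroids_a)
  cb <- extract_centers(centroids_b)
  if (ncol(ca) != ncol(cb)) stop("centroid matrices have different numbers of variables")
  p <- ncol(ca)
  d <- outer(seq_len(nrow(ca)), seq_len(nrow(cb)),
             Vectorize(function(i, j) sum((ca[i, ] - cb[j, ])^2) / p))
  pairs <- NULL; total <- NA_real_
  if (nrow(ca) == nrow(cb)) {
    sol <- min_cost_assignment(d)
    pairs <- data.frame(cluster_a = seq_len(nrow(ca)), cluster_b = sol$assignment,
                        ased = d[cbind(seq_len(nrow(ca)), sol$assignment)])
    pairs <- pairs[order(pairs$ased), ]
    rownames(pairs) <- NULL
    total <- sol$total
  }
  list(ased = d, pairs = pairs, total = total)
}

extract_centers <- function(x) {
  if (inherits(x, "kcenter_fit")) return(x$centers)
  as.matrix(x)
}

#' Exacon-style cross-tabulation with cell matching ratios
#'
#' Cross-tabulates two partitions of the same cases and computes, for every
#' cell, CMR = cell frequency / harmonic mean of the corresponding row and
#' column totals = n_ab (r_a + c_b) / (2 r_a c_b).  CMR is 1 for perfectly
#' corresponding clusters and 0 for disjoint ones.
#'
#' @param labels_a,labels_b integer label vectors over the same case set and
#'   order.
#' @return list: \code{table} (contingency), \code{cmr} matrix, and
#'   \code{matched} (the minimum-ASED pairing's CMRs when centroid matching
#'   information is attached later; here the per-cell matrix is the product).
#' @export
exacon_cmr <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("partitions cover different case sets")
  pa <- as_partition(labels_a); pb <- as_partition(labels_b)
  tab <- table(factor(pa$labels, levels = seq_len(pa$k)),
               factor(pb$labels, levels = seq_len(pb$k)))
  r <- rowSums(tab); cc <- colSums(tab)
  if (any(r == 0) || any(cc == 0)) stop("empty cluster in a partition")
  cmr <- tab * outer(r, cc, function(a, b) (a + b) / (2 * a * b))
  list(table = unclass(tab), cmr = unclass(cmr))
}

#' Matched-pair agreement of two cluster solutions
#'
#' Convenience wrapper combining \code{\link{centroid_match}} on the two
#' solutions' centroids with \code{\link{exacon_cmr}} on their labels: each
#' matched centroid pair is annotated with its ASED and its CMR.
#'
#' @param x data matrix both solutions were fitted on (used to recompute
#'   centroids from labels when fits are not supplied).
#' @param labels_a,labels_b label vectors.
#' @return data.frame: cluster_a, cluster_b, ased, cmr (sorted by ased).
#' @export
match_solutions <- function(x, labels_a, labels_b) {
  x <- as_data_matrix(x)
  pa <- as_partition(labels_a, nrow(x)); pb <- as_partition(labels_b, nrow(x))
  ca <- centroids_of(x, pa$labels, pa$k)
  cb <- centroids_of(x, pb$labels, pb$k)
  cm <- centroid_match(ca, cb)
  xc <- exacon_cmr(pa$labels, pb$labels)
  if (is.null(cm$pairs)) stop("solutions have different k; no one-to-one matching")
  cm$pairs$cmr <- xc$cmr[cbind(cm$pairs$cluster_a, cm$pairs$cluster_b)]
  cm$pairs
}
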