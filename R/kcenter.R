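#' K-center partitioning cluster analysis
#'
#' One front door to the three partitioning families: k-means (Hartigan-Wong,
#' MacQueen, or Lloyd-Forgy batch algorithm; objective = total within-cluster
#' sum of squares), PAM k-medoids (BUILD then SWAP; objective = sum of
#' case-to-medoid distances; medoids are actual cases), and k-medians
#' (alternating nearest-center assignment and within-cluster geometric
#' medians via Weiszfeld iteration; objective = sum of Euclidean distances to
#' centers).  All stochastic methods start from k distinct cases sampled
#' uniformly under the run seed and keep the best of \code{n_starts} runs by
#' objective; PAM's BUILD phase is deterministic, so it runs once.
#'
#' @param x numeric case-by-variable matrix (standardization recommended; a
#'   warning is issued otherwise).
#' @param k number of clusters, 2 <= k < n.
#' @param algorithm one of \code{"hartigan_wong"}, \code{"macqueen"},
#'   \code{"lloyd_forgy"}, \code{"pam"}, \code{"kmedians"}.
#' @param n_starts random restarts (default 10 for the stochastic methods,
#'   forced to 1 for pam).
#' @param max_iter iteration cap per start.
#' @param tol convergence tolerance on the relative objective change
#'   (kmedians only; kmeans converges by assignment stability).
#' @param seed RNG seed; fixed seed gives a bit-stable partition.
#' @param plusplus use k-means++ seeding instead of uniform case sampling
#'   (off by default).
#' @return object of class \code{"kcenter_fit"}: labels (canonical 1..k),
#'   sizes, centers, objective, medoid indices (pam), per-cluster HC when the
#'   data are standardized, and the method metadata.
#' @export
kcenter <- function(x, k, algorithm = "hartigan_wong", n_starts = 10L,
                    max_iter = 100L, tol = 1e-8, seed = 1L, plusplus = FALSE) {
  algorithm <- match.arg(algorithm, c("hartigan_wong", "macqueen",
                                      "lloyd_forgy", "pam", "kmedians"))
  x <- as_data_matrix(x)
  if (anyNA(x)) stop("missing values present; run preprocessing first")
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 2L || k >= n) stop("need 2 <= k < n")
  if (!is_standardized(x)) warning("x does not look standardized; the study pipeline clusters z-scores")
  set.seed(seed)
  fit <- switch(algorithm,
    pam      = fit_pam(x, k),
    kmedians = best_of_starts(x, k, n_starts, function(init) {
                 fit_kmedians(x, k, init, max_iter, tol)
               }, plusplus),
    best_of_starts(x, k, n_starts, function(init) {
      fit_kmeans_once(x, k, init, algorithm, max_iter)
    }, plusplus)
  )
  labels <- canonical_labels(fit$labels)
  first_seen <- unique(fit$labels)
  centers <- fit$centers[first_seen, , drop = FALSE]
  rownames(centers) <- NULL
  if (!is.null(fit$medoids)) fit$medoids <- fit$medoids[first_seen]
  hc <- if (is_standardized(x)) cluster_hc(x, labels)$hc else NULL
  structure(list(labels = labels, k = k, sizes = tabulate(labels, k),
                 centers = centers, objective = fit$objective,
                 medoids = fit$medoids, hc_per_cluster = hc,
                 algorithm = algorithm, n_starts = fit$n_starts,
                 seed = seed, iterations = fit$iterations, n = n),
            class = "kcenter_fit")
}

#' @export
print.kcenter_fit <- function(x, ...) {
  cat(sprintf("k-center solution: %s, k = %d, n = %d\n", x$algorithm, x$k, x$n))
  cat(sprintf("  objective = %.6g   sizes: %s\n", x$objective,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' @export
summary.kcenter_fit <- function(object, ...) {
  cat(sprintf("k-center solution (%s), k = %d, best of %s start(s), seed %d\n",
              object$algorithm, object$k, object$n_starts, object$seed))
  tab <- data.frame(cluster = seq_len(object$k), size = object$sizes)
  if (!is.null(object$hc_per_cluster)) tab$HC <- round(object$hc_per_cluster, 3)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @export
coef.kcenter_fit <- function(object, ...) object$centers

sample_init <- function(x, k, plusplus) {
  n <- nrow(x)
  if (!plusplus) return(distinct_case_sample(x, k))
  # k-means++ seeding
  idx <- sample.int(n, 1L)
  for (j in 2L:k) {
    d2 <- apply(x, 1L, function(r) min(colSums((t(x[idx, , drop = FALSE]) - r)^2)))
    d2[idx] <- 0
    if (sum(d2) <= 0) idx <- c(idx, sample(setdiff(seq_len(n), idx), 1L))
    else idx <- c(idx, sample.int(n, 1L, prob = d2))
  }
  x[idx, , drop = FALSE]
}

distinct_case_sample <- function(x, k) {
  n <- nrow(x)
  for (try in 1:100) {
    idx <- sample.int(n, k)
    cand <- x[idx, , drop = FALSE]
    if (nrow(unique(cand)) == k) return(cand)
  }
  stop("could not sample k distinct cases (too many duplicated rows)")
}

best_of_starts <- function(x, k, n_starts, one_fit, plusplus) {
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    init <- sample_init(x, k, plusplus)
    f <- one_fit(init)
    if (is.null(best) || f$objective < best$objective) best <- f
  }
  best$n_starts <- n_starts
  best
}

fit_kmeans_once <- function(x, k, init, algorithm, max_iter) {
  alg <- c(hartigan_wong = "Hartigan-Wong", macqueen = "MacQueen",
           lloyd_forgy = "Lloyd")[[algorithm]]
  km <- tryCatch(
    suppressWarnings(stats::kmeans(x, centers = init, iter.max = max_iter,
                                   nstart = 1L, algorithm = alg)),
    error = function(e) NULL)
  if (is.null(km)) {
    # empty-cluster failure: re-seed the offending center at the farthest case
    km <- suppressWarnings(stats::kmeans(x, centers = reseed_farthest(x, init),
                                         iter.max = max_iter, nstart = 1L,
                                         algorithm = alg))
  }
  list(labels = km$cluster, centers = km$centers, objective = km$tot.withinss,
       medoids = NULL, iterations = km$iter)
}

reseed_farthest <- function(x, init) {
  # replace the most redundant center (closest to another center) by the case
  # farthest from all current centers
  d2 <- apply(x, 1L, function(r) min(colSums((t(init) - r)^2)))
  cd <- as.matrix(stats::dist(init)); diag(cd) <- Inf
  init[which.min(apply(cd, 1L, min)), ] <- x[which.max(d2), ]
  init
}

fit_pam <- function(x, k) {
  pm <- cluster::pam(x, k = k, metric = "euclidean", stand = FALSE,
                     keep.diss = FALSE, keep.data = FALSE)
  labels <- unname(pm$clustering)
  med_idx <- unname(pm$id.med)
  dmed <- sqrt(pmax(outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(x[med_idx, , drop = FALSE]) +
                 outer(rep(1, nrow(x)), rowSums(x[med_idx, , drop = FALSE]^2)), 0))
  obj <- sum(dmed[cbind(seq_len(nrow(x)), labels)])
  list(labels = labels, centers = x[med_idx, , drop = FALSE], objective = obj,
       medoids = med_idx, iterations = NA_integer_, n_starts = 1L)
}

#' Geometric median via Weiszfeld iteration
#'
#' Minimizes the sum of Euclidean distances to the rows of \code{x}.  When an
#' iterate lands on a data point the standard subgradient (Vardi-Zhang)
#' correction decides whether that point is the optimum or how to step off it.
#'
#' @param x numeric matrix of points (rows).
#' @param tol convergence tolerance on the step size (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @return numeric vector, the geometric median.
#' @export
geometric_median <- function(x, tol = 1e-8, max_iter = 200L) {
  x <- unname(as.matrix(x))
  if (nrow(x) == 1L) return(drop(x[1L, ]))
  y <- colMeans(x)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(x, 2L, y, "-")^2))
    on_pt <- d < 1e-12
    if (any(on_pt)) {
      # Vardi-Zhang: y coincides with data point x_j
      others <- !on_pt
      if (!any(others)) return(y)
      w <- 1 / d[others]
      Tn <- colSums(x[others, , drop = FALSE] * w) / sum(w)
      Rvec <- colSums(sweep(x[others, , drop = FALSE], 2L, y, "-") / d[others])
      r <- sqrt(sum(Rvec^2))
      eta <- sum(on_pt)
      if (r <= eta) return(y)
      ynew <- max(0, 1 - eta / r) * Tn + min(1, eta / r) * y
    } else {
      w <- 1 / d
      ynew <- colSums(x * w) / sum(w)
    }
    if (sqrt(sum((ynew - y)^2)) < tol) return(ynew)
    y <- ynew
  }
  y
}

fit_kmedians <- function(x, k, init, max_iter, tol) {
  centers <- init
  obj_old <- Inf
  labels <- NULL
  for (it in seq_len(max_iter)) {
    d <- sqrt(pmax(outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
                     outer(rep(1, nrow(x)), rowSums(centers^2)), 0))
    labels <- max.col(-d, ties.method = "first")
    # re-seed empty clusters at the farthest case
    for (c in which(tabulate(labels, k) == 0L)) {
      far <- which.max(d[cbind(seq_len(nrow(x)), labels)])
      labels[far] <- c
    }
    for (c in seq_len(k)) {
      centers[c, ] <- geometric_median(x[labels == c, , drop = FALSE])
    }
    obj <- sum(sqrt(rowSums((x - centers[labels, , drop = FALSE])^2)))
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(1, obj_old)) break
    obj_old <- obj
  }
  list(labels = labels, centers = centers, objective = obj,
       medoids = NULL, iterations = it)
}
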