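#' Agglomerative hierarchical cluster analysis
#'
#' Classic Lance-Williams agglomeration over one of eight linkage methods and
#' one of the supported case distances.  \code{ward} follows the ward.D
#' convention on the supplied (intended squared-Euclidean) distances, so the
#' default \code{squared_euclidean} distance with \code{ward} reproduces the
#' usual Ward error-sum-of-squares fusion.  \code{flexible_beta} uses
#' alpha_i = alpha_j = (1 - beta)/2, gamma = 0 with Milligan's recommended
#' default beta = -0.25.
#'
#' Centroid and median linkage expect squared Euclidean distances (a warning
#' is recorded otherwise) and may produce height inversions; these are
#' reported via \code{inversions}, not treated as errors.
#'
#' @param x numeric case-by-variable matrix, or a precomputed \code{dist} /
#'   symmetric distance matrix (then \code{spec} is ignored).
#' @param method linkage: one of \code{"average"}, \code{"single"},
#'   \code{"complete"}, \code{"centroid"}, \code{"median"}, \code{"ward"},
#'   \code{"flexible_beta"}, \code{"mcquitty"}.
#' @param spec a \code{\link{distance_spec}} or distance name used when
#'   \code{x} is raw data (default squared Euclidean, the study convention).
#' @param beta flexible-beta parameter in (-1, 1), default -0.25.
#' @return object of class \code{"dendro"}: merge table, heights, order,
#'   direction ("agglomerative"), method and distance metadata.
#' @seealso \code{\link{dhca}}, \code{\link{cut_tree}}, \code{\link{qc_table}}
#' @export
ahca <- function(x, method = "ward", spec = distance_spec("squared_euclidean"),
                 beta = -0.25) {
  method <- match.arg(method, c("average", "single", "complete", "centroid",
                                "median", "ward", "flexible_beta", "mcquitty"))
  if (is.character(spec)) spec <- distance_spec(spec)
  d <- as_dist_input(x, spec)
  if (anyNA(d) || any(!is.finite(d))) stop("non-finite distances")
  if (method %in% c("centroid", "median", "ward") && spec$name != "squared_euclidean" &&
      !inherits(x, "dist") && !is_square_matrix(x)) {
    warning(method, " linkage expects squared Euclidean distances")
  }
  if (method == "flexible_beta") {
    if (beta <= -1 || beta >= 1) stop("beta must be in (-1, 1)")
    alpha <- (1 - beta) / 2
    h <- stats::as.hclust(cluster::agnes(d, diss = TRUE, method = "flexible",
                                         par.method = alpha, keep.diss = FALSE,
                                         keep.data = FALSE))
  } else {
    hm <- c(average = "average", single = "single", complete = "complete",
            centroid = "centroid", median = "median", ward = "ward.D",
            mcquitty = "mcquitty")[[method]]
    h <- stats::hclust(d, method = hm)
  }
  new_dendro(h, direction = "agglomerative", method = method, spec = spec,
             beta = if (method == "flexible_beta") beta else NULL)
}

#' Divisive hierarchical cluster analysis (DIANA)
#'
#' Kaufman-Rousseeuw divisive analysis: at each step the cluster with the
#' largest diameter is split by the splinter procedure (the seed object has
#' the largest average dissimilarity; objects migrate to the splinter group
#' while their average dissimilarity to it is smaller than to the remainder).
#' The split height is the diameter of the divided cluster.  The divisive
#' tree is re-expressed in the agglomerative merge-table form so that
#' \code{\link{cut_tree}} and exports are shared with \code{\link{ahca}}.
#'
#' @inheritParams ahca
#' @return object of class \code{"dendro"} with direction "divisive".
#' @export
dhca <- function(x, spec = distance_spec("squared_euclidean")) {
  if (is.character(spec)) spec <- distance_spec(spec)
  d <- as_dist_input(x, spec)
  if (anyNA(d) || any(!is.finite(d))) stop("non-finite distances")
  di <- cluster::diana(d, diss = TRUE, keep.diss = FALSE, keep.data = FALSE)
  new_dendro(stats::as.hclust(di), direction = "divisive", method = "diana",
             spec = spec)
}

as_dist_input <- function(x, spec) {
  if (inherits(x, "dist")) return(x)
  if (is_square_matrix(x)) return(stats::as.dist(x))
  x <- as_data_matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 cases")
  if (anyNA(x)) stop("missing values present; run preprocessing first")
  dist_object(x, spec)
}

is_square_matrix <- function(x) {
  is.matrix(x) && nrow(x) == ncol(x) && nrow(x) > 1L &&
    isTRUE(all.equal(unname(x), unname(t(x)), tolerance = 1e-12)) &&
    all(abs(diag(x)) < 1e-12)
}

new_dendro <- function(h, direction, method, spec, beta = NULL) {
  inv <- sum(diff(h$height) < -1e-12)
  structure(list(merge = h$merge, height = h$height, order = h$order,
                 labels = h$labels, n = length(h$order),
                 direction = direction, method = method,
                 distance = spec$name, minkowski_power = spec$minkowski_power,
                 beta = beta, inversions = inv),
            class = "dendro")
}

#' @export
print.dendro <- function(x, ...) {
  cat(sprintf("%s hierarchical clustering (%s linkage, %s distance)\n",
              x$direction, x$method, x$distance))
  cat(sprintf("  cases: %d   merge heights: %.4g .. %.4g\n",
              x$n, min(x$height), max(x$height)))
  if (x$inversions > 0) {
    cat(sprintf("  note: %d height inversion(s) present\n", x$inversions))
  }
  invisible(x)
}

#' @export
as.hclust.dendro <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = x$distance),
            class = "hclust")
}

#' @export
plot.dendro <- function(x, ...) plot(stats::as.hclust(x), ...)

#' Cut a dendrogram into k clusters
#'
#' Returns the partition after exactly n - k agglomerations (equivalently
#' k - 1 divisions for a divisive tree), i.e. the clusters a horizontal line
#' intersecting k vertical segments of the dendrogram would produce.  Labels
#' are renumbered 1..k by first case appearance.
#'
#' @param dend a \code{"dendro"} object.
#' @param k number of clusters, 1 <= k <= n.
#' @return integer label vector of length n.
#' @export
cut_tree <- function(dend, k) {
  stopifnot(inherits(dend, "dendro"))
  k <- as.integer(k)
  if (k < 1L || k > dend$n) stop("k out of 1..n range")
  labs <- stats::cutree(stats::as.hclust(dend), k = k)
  canonical_labels(unname(labs))
}

#' Total within-cluster sum of squares over a k range
#'
#' TotalWSS(k) = sum over clusters of the squared Euclidean distances of
#' members to their cluster centroid; the compactness series behind the
#' elbow ("knee") plot.
#'
#' @param x numeric data matrix.
#' @param partitions list of label vectors (e.g. from \code{cut_tree} over a
#'   k range), or a \code{"dendro"} with \code{k_range}.
#' @param k_range ks to cut when \code{partitions} is a dendrogram.
#' @return data.frame with columns k, total_wss.
#' @export
wss_series <- function(x, partitions, k_range = NULL) {
  x <- as_data_matrix(x)
  if (inherits(partitions, "dendro")) {
    if (is.null(k_range)) stop("supply k_range with a dendrogram")
    partitions <- lapply(k_range, function(k) cut_tree(partitions, k))
  }
  ks <- vapply(partitions, function(l) max(as_partition(l, nrow(x))$labels), integer(1L))
  wss <- vapply(partitions, function(l) total_wss(x, l), numeric(1L))
  data.frame(k = ks, total_wss = wss)
}

# sum over clusters of squared euclidean distances to the centroid
total_wss <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xc <- x[idx, , drop = FALSE]
    sum(sweep(xc, 2L, colMeans(xc), "-")^2)
  }, numeric(1L)))
}

#' Export a dendrogram merge table
#'
#' Writes the (child_a, child_b, height, size) merge table as TSV for
#' external plotting; negative children are leaves, positive ones earlier
#' merges, matching the hclust convention.
#'
#' @param dend a \code{"dendro"} object.
#' @param path output file; when NULL the data.frame is returned invisibly
#'   without writing.
#' @export
export_merge_table <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "dendro"))
  size <- integer(nrow(dend$merge))
  sz <- function(ch, i) if (ch < 0) 1L else size[ch]
  for (i in seq_len(nrow(dend$merge))) {
    size[i] <- sz(dend$merge[i, 1], i) + sz(dend$merge[i, 2], i)
  }
  tab <- data.frame(child_a = dend$merge[, 1], child_b = dend$merge[, 2],
                    height = dend$height, size = size)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}
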