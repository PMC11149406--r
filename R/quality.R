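#' Per-cluster homogeneity coefficients (HC)
#'
#' HC of a cluster is the mean pairwise ASED among its members, equivalently
#' 2 * WSS_c / (p * (n_c - 1)); a singleton has HC = 0.  On standardized data
#' a random (structureless) cluster has HC about 2, identical members give 0,
#' so lower is more homogeneous.  HCmean is the size-weighted average
#' sum(n_c * HC_c) / n.
#'
#' @param x standardized numeric matrix.
#' @param labels integer cluster labels.
#' @return list: \code{hc} (per cluster), \code{hc_mean}, \code{hc_min},
#'   \code{hc_max}, \code{sizes}.
#' @export
cluster_hc <- function(x, labels) {
  x <- as_data_matrix(x)
  part <- as_partition(labels, nrow(x))
  p <- ncol(x)
  hc <- vapply(seq_len(part$k), function(c) {
    idx <- which(part$labels == c)
    if (length(idx) < 2L) return(0)
    xc <- x[idx, , drop = FALSE]
    wss <- sum(sweep(xc, 2L, colMeans(xc), "-")^2)
    2 * wss / (p * (length(idx) - 1L))
  }, numeric(1L))
  list(hc = hc, hc_mean = sum(part$sizes * hc) / sum(part$sizes),
       hc_min = min(hc), hc_max = max(hc), sizes = part$sizes)
}

#' Explained error sum of squares percentage (EESS\%)
#'
#' 100 * (T - TotalWSS) / T with T the total sum of squared deviations from
#' the grand centroid: the multivariate generalization of the eta-squared
#' effect size.  100 for the all-singleton partition, 0 for a single cluster.
#'
#' @inheritParams cluster_hc
#' @export
eess_pct <- function(x, labels) {
  x <- as_data_matrix(x)
  part <- as_partition(labels, nrow(x))
  tss <- sum(sweep(x, 2L, colMeans(x), "-")^2)
  if (tss <= 0) stop("zero total sum of squares")
  100 * (tss - total_wss(x, part$labels)) / tss
}

#' Modified Xie-Beni separation index (XBmod)
#'
#' Separation measure: the minimum over cluster pairs of the ASED between
#' centroids, minus HCmean.  Positive and large for well-separated compact
#' solutions, negative when clusters overlap.  The exact published formula
#' lives in the quality-coefficient literature this reconstruction follows;
#' it is isolated here so it can be swapped out wholesale.
#'
#' @inheritParams cluster_hc
#' @export
xbmod <- function(x, labels) {
  x <- as_data_matrix(x)
  part <- as_partition(labels, nrow(x))
  if (part$k < 2L) stop("need k >= 2")
  cent <- centroids_of(x, part$labels, part$k)
  dc <- as.matrix(stats::dist(cent))^2 / ncol(x)
  min(dc[upper.tri(dc)]) - cluster_hc(x, part$labels)$hc_mean
}

centroids_of <- function(x, labels, k) {
  t(vapply(seq_len(k), function(c) colMeans(x[labels == c, , drop = FALSE]),
           numeric(ncol(x))))
}

#' Mean silhouette width
#'
#' Rousseeuw silhouette s_i = (b_i - a_i) / max(a_i, b_i) averaged over
#' cases; singletons contribute 0.  Computed from the full Euclidean (or
#' supplied) distance matrix via \code{cluster::silhouette}.
#'
#' @param d a \code{dist}, a symmetric distance matrix, or raw data (then
#'   Euclidean distances are used).
#' @param labels integer cluster labels.
#' @export
silhouette_mean <- function(d, labels) {
  if (!inherits(d, "dist")) {
    d <- if (is_square_matrix(d)) stats::as.dist(d) else stats::dist(as_data_matrix(d))
  }
  part <- as_partition(labels, attr(d, "Size"))
  if (part$k < 2L) stop("need k >= 2")
  sil <- cluster::silhouette(part$labels, d)
  mean(sil[, "sil_width"])
}

#' Homogeneity percentages
#'
#' HomT = percentage of cases belonging to clusters with HC strictly below T,
#' at the four conventional levels T = 0.10, 0.20, 0.30, 0.50.
#'
#' @param hc per-cluster HC values.
#' @param sizes per-cluster sizes.
#' @param thresholds homogeneity levels (default c(0.10, 0.20, 0.30, 0.50)).
#' @return named numeric vector (Hom10, Hom20, Hom30, Hom50 by default).
#' @export
homogeneity_percentages <- function(hc, sizes, thresholds = c(0.10, 0.20, 0.30, 0.50)) {
  if (length(hc) != length(sizes)) stop("hc and sizes lengths differ")
  n <- sum(sizes)
  out <- vapply(thresholds, function(t) 100 * sum(sizes[hc < t]) / n, numeric(1L))
  names(out) <- paste0("Hom", formatC(100 * thresholds, format = "d"))
  out
}

#' Quality-coefficient set for one partition
#'
#' Bundles every quality coefficient of a cluster solution: EESS\%, XBmod,
#' HCmean/min/max, mean silhouette, the four homogeneity percentages,
#' TotalWSS and k.
#'
#' @inheritParams cluster_hc
#' @param silhouette compute the mean silhouette too (O(n^2); default TRUE).
#' @return object of class \code{"qc_set"} (a named list).
#' @export
qc_set <- function(x, labels, silhouette = TRUE) {
  x <- as_data_matrix(x)
  part <- as_partition(labels, nrow(x))
  hcres <- cluster_hc(x, part$labels)
  hom <- homogeneity_percentages(hcres$hc, hcres$sizes)
  out <- list(k = part$k,
              EESS_pct = eess_pct(x, part$labels),
              XBmod = if (part$k >= 2L) xbmod(x, part$labels) else NA_real_,
              HCmean = hcres$hc_mean, HCmin = hcres$hc_min, HCmax = hcres$hc_max,
              mean_silhouette = if (silhouette && part$k >= 2L)
                silhouette_mean(x, part$labels) else NA_real_,
              total_wss = total_wss(x, part$labels))
  out <- c(out, as.list(hom))
  structure(out, class = "qc_set")
}

#' @export
print.qc_set <- function(x, ...) {
  cat(sprintf("QC set (k = %d): EESS%% = %.1f  XBmod = %.3f  HCmean = %.3f  [%.3f, %.3f]\n",
              x$k, x$EESS_pct, x$XBmod, x$HCmean, x$HCmin, x$HCmax))
  cat(sprintf("  silhouette = %s   Hom10/20/30/50 = %.1f / %.1f / %.1f / %.1f\n",
              ifelse(is.na(x$mean_silhouette), "NA", sprintf("%.3f", x$mean_silhouette)),
              x$Hom10, x$Hom20, x$Hom30, x$Hom50))
  invisible(x)
}

#' QC summary table over a range of solutions
#'
#' One row per k with the columns of the conventional summary layout
#' (EESS\%, XBmod, HCmean, HCmin, HCmax), for a dendrogram cut over
#' \code{k_range} or for a named list of label vectors.
#'
#' @param x standardized data matrix.
#' @param solutions a \code{"dendro"} object or a list of label vectors.
#' @param k_range ks to cut when \code{solutions} is a dendrogram.
#' @param silhouette include the mean silhouette column (default FALSE).
#' @return data.frame, one row per solution.
#' @export
qc_table <- function(x, solutions, k_range = NULL, silhouette = FALSE) {
  x <- as_data_matrix(x)
  if (inherits(solutions, "dendro")) {
    if (is.null(k_range)) stop("supply k_range with a dendrogram")
    solutions <- lapply(k_range, function(k) cut_tree(solutions, k))
  }
  rows <- lapply(solutions, function(l) {
    q <- qc_set(x, l, silhouette = silhouette)
    data.frame(k = q$k, EESS_pct = q$EESS_pct, XBmod = q$XBmod,
               HCmean = q$HCmean, HCmin = q$HCmin, HCmax = q$HCmax,
               mean_silhouette = q$mean_silhouette,
               Hom10 = q$Hom10, Hom20 = q$Hom20, Hom30 = q$Hom30, Hom50 = q$Hom50)
  })
  out <- do.call(rbind, rows)
  if (!silhouette) out$mean_silhouette <- NULL
  out
}

#' Acceptability flags for a QC set
#'
#' The conventional acceptance rule for an overall cluster structure:
#' EESS\% > 70, XBmod > 0.50 and HCmean < 0.50 (strict inequalities), with
#' configurable thresholds; returns per-criterion flags and their AND.
#'
#' @param qc a \code{\link{qc_set}} (or list with EESS_pct, XBmod, HCmean).
#' @param eess_min,xbmod_min,hcmean_max thresholds.
#' @return named logical vector: eess, xbmod, hcmean, acceptable.
#' @export
acceptability <- function(qc, eess_min = 70, xbmod_min = 0.50, hcmean_max = 0.50) {
  fl <- c(eess = qc$EESS_pct > eess_min,
          xbmod = qc$XBmod > xbmod_min,
          hcmean = qc$HCmean < hcmean_max)
  c(fl, acceptable = all(fl))
}

#' Pattern coding of standardized cluster means
#'
#' Codes each standardized cluster mean into the conventional symbols:
#' \code{"."} for |z| < 0.25, \code{"(H)"}/\code{"(L)"} for 0.25 <= |z| < 0.5,
#' \code{"H"}/\code{"L"} for 0.5 <= |z| < 1, then one \code{"+"} per further
#' 0.5 up to \code{"++++"} at |z| >= 2.5.  More pluses indicate more extreme
#' means.
#'
#' @inheritParams cluster_hc
#' @param breaks band edges (increasing, default c(0.25, 0.5, 1, 1.5, 2, 2.5)).
#' @return data.frame: one row per cluster, coded symbol per variable plus
#'   CLsize and HC columns; attribute \code{means} holds the raw z means.
#' @export
pattern_table <- function(x, labels, breaks = c(0.25, 0.5, 1, 1.5, 2, 2.5)) {
  x <- as_data_matrix(x)
  part <- as_partition(labels, nrow(x))
  cent <- centroids_of(x, part$labels, part$k)
  codes <- apply(cent, c(1L, 2L), pattern_code, breaks = breaks)
  hcres <- cluster_hc(x, part$labels)
  out <- data.frame(cluster = paste0("CL", seq_len(part$k)), codes,
                    CLsize = part$sizes, HC = hcres$hc,
                    stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out)[1L + seq_len(ncol(x))] <- colnames(x)
  attr(out, "means") <- cent
  out
}

pattern_code <- function(z, breaks = c(0.25, 0.5, 1, 1.5, 2, 2.5)) {
  a <- abs(z)
  if (a < breaks[1]) return(".")
  side <- if (z > 0) "H" else "L"
  if (a < breaks[2]) return(paste0("(", side, ")"))
  band <- findInterval(a, breaks)  # 2 -> bare letter, 3 -> one plus, ...
  paste0(side, strrep("+", band - 2L))
}
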