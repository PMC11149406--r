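#' Coerce input to a numeric case-by-variable matrix
#'
#' Accepts a numeric matrix or data frame of quantitative scores and returns a
#' plain numeric matrix with case ids as rownames and variable names as
#' colnames.  Standardization state travels along as attributes
#' (\code{standardized}, \code{std_center}, \code{std_scale}) so that cluster
#' centroids can be reported on either scale.
#'
#' @param x numeric matrix or data frame (cases in rows, variables in columns).
#' @param vars optional character vector selecting columns.
#' @return numeric matrix with dimnames.
#' @export
as_data_matrix <- function(x, vars = NULL) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1L))
    if (!all(num)) {
      stop("non-numeric columns: ", paste(names(x)[!num], collapse = ", "))
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix or data frame")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (!is.null(vars)) {
    miss <- setdiff(vars, colnames(x))
    if (length(miss)) stop("unknown variables: ", paste(miss, collapse = ", "))
    x <- x[, vars, drop = FALSE]
  }
  x
}

#' Standardize columns to z-scores
#'
#' Centers and scales every column to sample mean 0 and sample standard
#' deviation 1, using the n-1 denominator.  The original per-column mean and
#' sd are kept in attributes for back-transformation; standardizing an
#' already-standardized matrix is a no-op up to numerical error.
#'
#' @param x numeric matrix or data frame; no missing values allowed (resolve
#'   them with the preprocessing functions first).
#' @return standardized matrix with attributes \code{standardized = TRUE},
#'   \code{std_center}, \code{std_scale}.
#' @export
standardize <- function(x) {
  x <- as_data_matrix(x)
  if (anyNA(x)) stop("missing values present; run preprocessing (build_scales/complete_cases_on) first")
  s <- apply(x, 2L, stats::sd)
  if (any(s <= 0)) {
    stop("constant column(s): ", paste(colnames(x)[s <= 0], collapse = ", "))
  }
  m <- colMeans(x)
  z <- sweep(sweep(x, 2L, m, "-"), 2L, s, "/")
  attr(z, "standardized") <- TRUE
  attr(z, "std_center") <- m
  attr(z, "std_scale") <- s
  z
}

#' @export
is_standardized <- function(x) isTRUE(attr(x, "standardized"))

#' Distance specification
#'
#' @param name one of \code{"squared_euclidean"}, \code{"euclidean"},
#'   \code{"manhattan"}, \code{"canberra"}, \code{"maximum"},
#'   \code{"minkowski"}, \code{"ased"}.  ASED is the squared Euclidean
#'   distance divided by the number of variables, which puts the
#'   nearest-neighbour outlier threshold and the ~2 random-pair baseline on a
#'   scale free of the variable count.
#' @param minkowski_power Minkowski exponent, default 2 (i.e. euclidean).
#' @return object of class \code{"distance_spec"}.
#' @export
distance_spec <- function(name = "squared_euclidean", minkowski_power = 2) {
  name <- match.arg(name, c("squared_euclidean", "euclidean", "manhattan",
                            "canberra", "maximum", "minkowski", "ased"))
  if (!is.numeric(minkowski_power) || minkowski_power <= 0) {
    stop("minkowski_power must be > 0")
  }
  structure(list(name = name, minkowski_power = minkowski_power),
            class = "distance_spec")
}

#' Pairwise distance matrix
#'
#' Computes the full symmetric case-by-case distance matrix under a
#' \code{\link{distance_spec}}.  Squared Euclidean and ASED are derived from
#' the Euclidean distances of \code{stats::dist}; the remaining metrics map
#' directly onto \code{stats::dist} methods.
#'
#' @param x numeric matrix (no missing values).
#' @param spec a \code{\link{distance_spec}} or a distance name.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
pairwise_distances <- function(x, spec = distance_spec()) {
  if (is.character(spec)) spec <- distance_spec(spec)
  x <- as_data_matrix(x)
  if (anyNA(x)) stop("missing values present; run preprocessing first")
  d <- dist_object(x, spec)
  as.matrix(d)
}

# stats::dist based engine shared by the clustering fitters; returns a "dist"
dist_object <- function(x, spec) {
  p <- ncol(x)
  switch(spec$name,
    squared_euclidean = stats::dist(x, method = "euclidean")^2,
    ased              = stats::dist(x, method = "euclidean")^2 / p,
    euclidean         = stats::dist(x, method = "euclidean"),
    manhattan         = stats::dist(x, method = "manhattan"),
    canberra          = stats::dist(x, method = "canberra"),
    maximum           = stats::dist(x, method = "maximum"),
    minkowski         = stats::dist(x, method = "minkowski", p = spec$minkowski_power)
  )
}

#' Average squared Euclidean distance between two vectors
#'
#' ASED(x, y) = squared Euclidean distance / number of variables.  For two
#' independent standardized cases its expectation is 2, which anchors both the
#' homogeneity-coefficient baseline and the tau = 0.7 outlier screen.
#'
#' @param x,y numeric vectors of equal length.
#' @export
ased <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  sum((x - y)^2) / length(x)
}

#' Validate and summarize a partition
#'
#' @param labels integer cluster labels.
#' @param n expected number of cases (optional check).
#' @return list with \code{labels} (1..k, renumbered by first appearance),
#'   \code{k}, \code{sizes}.
#' @export
as_partition <- function(labels, n = NULL) {
  if (!is.null(n) && length(labels) != n) stop("labels length != n")
  if (anyNA(labels)) stop("NA labels")
  labels <- match(labels, unique(labels))
  k <- max(labels)
  sizes <- tabulate(labels, nbins = k)
  if (any(sizes == 0L)) stop("empty cluster")
  list(labels = labels, k = k, sizes = sizes)
}

# canonical relabeling by first appearance (used for determinism guarantees)
canonical_labels <- function(labels) match(labels, unique(labels))
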