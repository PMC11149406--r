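#' Read a rectangular case-by-variable dataset
#'
#' Reads a CSV or TSV table with a header row into a numeric matrix, parsing
#' empty cells, "NA" and an optional sentinel as missing.  The separator is
#' taken from the extension (.tsv/.txt = tab, otherwise comma) unless given.
#'
#' @param path input file.
#' @param vars optional column selection.
#' @param sentinel optional missing-value sentinel (e.g. "-9999").
#' @param sep field separator; NULL = infer from extension.
#' @param id_col optional name of a case-id column (kept as rownames).
#' @return numeric matrix with a missing summary in attributes
#'   \code{n_missing}.
#' @export
read_dataset <- function(path, vars = NULL, sentinel = NULL, sep = NULL,
                         id_col = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  na <- c("", "NA", sentinel)
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                          check.names = FALSE, stringsAsFactors = FALSE)
  dup <- duplicated(names(df))
  if (any(dup)) stop("duplicate column names: ", paste(unique(names(df)[dup]), collapse = ", "))
  if (!is.null(id_col)) {
    rownames(df) <- as.character(df[[id_col]])
    df[[id_col]] <- NULL
  }
  bad <- !vapply(df, is.numeric, logical(1L))
  if (any(bad)) {
    col <- names(df)[bad][1L]
    row <- which(!is.na(df[[col]]) & is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
    stop(sprintf("non-numeric cell at row %s, column '%s'",
                 ifelse(is.na(row), "?", row), col))
  }
  x <- as_data_matrix(df, vars = vars)
  attr(x, "n_missing") <- sum(is.na(x))
  x
}

#' Append cluster-code (and uncertainty) columns to a data file
#'
#' Rewrites the input table with the original columns preserved verbatim
#' (cells are carried as text) and one integer column appended per named
#' partition, plus an optional uncertainty column.
#'
#' @param path_in,path_out input and output files (same separator rules as
#'   \code{\link{read_dataset}}).
#' @param partitions named list of integer label vectors, e.g.
#'   \code{list(clu7_kmeans = labels)}.
#' @param uncertainty optional named list of numeric vectors.
#' @param overwrite allow clobbering an existing column name.
#' @export
append_cluster_codes <- function(path_in, path_out, partitions,
                                 uncertainty = NULL, overwrite = FALSE) {
  sep <- if (grepl("\\.(tsv|txt)$", path_in, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path_in, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          na.strings = NULL)
  if (is.null(names(partitions)) || any(names(partitions) == "")) {
    stop("partitions must be a named list")
  }
  new_cols <- c(names(partitions), names(uncertainty))
  clash <- intersect(new_cols, names(df))
  if (length(clash) && !overwrite) {
    stop("column name collision: ", paste(clash, collapse = ", "))
  }
  for (nm in names(partitions)) {
    l <- partitions[[nm]]
    if (length(l) != nrow(df)) stop("partition length != row count for ", nm)
    df[[nm]] <- as.integer(l)
  }
  for (nm in names(uncertainty)) {
    u <- uncertainty[[nm]]
    if (length(u) != nrow(df)) stop("uncertainty length != row count for ", nm)
    df[[nm]] <- u
  }
  utils::write.table(df, path_out, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path_out)
}

#' Specification of a synthetic cluster typology
#'
#' Defines the planted-type generator that emulates the shape of the study
#' data: k types with centroid patterns in z-units, within-type spread,
#' mixing proportions, optional monotone right-skewing of chosen variables
#' (attachment-anxiety-like long right tails), and optional expansion of each
#' scale into Likert items.
#'
#' The default specification mirrors the published 7-type solution on four
#' scales: centroid signs follow the printed pattern table of the 7-cluster
#' partitioning solution, proportions follow its printed cluster sizes,
#' within-type sd is 0.5 and n = 800.
#'
#' @param n number of cases.
#' @param centroids k x p matrix of type centroids in z-units.
#' @param proportions mixing proportions (sum to 1).
#' @param sd within-type standard deviation (scalar or per-variable).
#' @param skew named/positional numeric vector of per-variable skew strengths
#'   (0 = none); positive values apply a monotone convex map producing a long
#'   right tail.
#' @param var_names variable names.
#' @return object of class \code{"typology_spec"}.
#' @export
typology_spec <- function(n = 800L,
                          centroids = default_centroids(),
                          proportions = default_proportions(),
                          sd = 0.5,
                          skew = NULL,
                          var_names = colnames(centroids)) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids); p <- ncol(centroids)
  if (length(proportions) != k) stop("proportions length != number of centroid rows")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (any(proportions <= 0)) stop("proportions must be positive")
  if (any(sd <= 0)) stop("sd must be > 0")
  if (is.null(var_names)) var_names <- paste0("V", seq_len(p))
  if (!is.null(skew) && length(skew) != p) stop("skew length != p")
  structure(list(n = as.integer(n), centroids = centroids,
                 proportions = proportions, sd = rep(sd, length.out = p),
                 skew = skew, var_names = var_names),
            class = "typology_spec")
}

# the printed 7-type centroid sign pattern mapped to band-midpoint z values
default_centroids <- function() {
  m <- rbind(
    c( 1.2,  0.0,  1.2, -0.35),
    c( 0.0, -0.35, 0.0, -0.35),
    c(-1.2, -0.35, -1.2, -0.35),
    c( 0.0,  0.7,  0.0,  0.35),
    c(-0.35, -0.35, 1.2,  1.2),
    c( 0.7,  2.7,  0.7,  2.2),
    c( 1.2,  0.7,  0.7,  0.7))
  colnames(m) <- c("AvoidMo", "AnxMo", "AvoidFa", "AnxFa")
  m
}

default_proportions <- function() {
  sizes <- c(101, 211, 205, 80, 51, 71, 74)
  sizes / sum(sizes)
}

#' Generate a synthetic typology dataset
#'
#' Draws type labels from the mixing proportions, case values from
#' per-type Gaussians around the centroid pattern, then (optionally) applies
#' a monotone skewing map per variable.  Seeded and fully reproducible.
#'
#' @param spec a \code{\link{typology_spec}}.
#' @param seed RNG seed.
#' @return list: \code{data} (n x p matrix), \code{labels} (true types,
#'   canonical 1..k).
#' @export
generate_typology <- function(spec = typology_spec(), seed = 1L) {
  stopifnot(inherits(spec, "typology_spec"))
  set.seed(seed)
  k <- nrow(spec$centroids); p <- ncol(spec$centroids)
  labels <- sample.int(k, spec$n, replace = TRUE, prob = spec$proportions)
  x <- spec$centroids[labels, , drop = FALSE] +
    matrix(stats::rnorm(spec$n * p), spec$n, p) %*% diag(spec$sd, p)
  if (!is.null(spec$skew)) {
    for (j in seq_len(p)) x[, j] <- skew_map(x[, j], spec$skew[j])
  }
  colnames(x) <- spec$var_names
  rownames(x) <- as.character(seq_len(spec$n))
  list(data = x, labels = labels)
}

# monotone convex map producing a long right tail; strength 0 = identity.
# exp-based: preserves order; on the default 7-type anxiety-like variables
# (which are already right-skewed by the planted extreme type) strength ~0.2
# yields overall skewness in the 1-2.2 range typical of attachment-anxiety
# scores.
skew_map <- function(z, strength) {
  if (is.null(strength) || strength == 0) return(z)
  (exp(strength * z) - 1) / strength
}

#' Expand scale scores into synthetic Likert items
#'
#' Turns each generated scale value into \code{m} item responses (value plus
#' rounding noise, clipped to the item range), so the truncation /
#' scale-construction / reliability pipeline can be exercised on synthetic
#' data.
#'
#' @param x matrix of scale scores (will be rescaled linearly into the item
#'   range).
#' @param m items per scale.
#' @param range item range (default 1..5).
#' @param noise_sd sd of the per-item noise before rounding.
#' @param seed RNG seed.
#' @return a \code{\link{likert_items}} object whose scale map groups the
#'   \code{m} items of each input column.
#' @export
itemize_scales <- function(x, m = 4L, range = c(1L, 5L), noise_sd = 0.7,
                           seed = 1L) {
  x <- as_data_matrix(x)
  set.seed(seed)
  p <- ncol(x)
  # map each column linearly onto the item range
  scaled <- apply(x, 2L, function(col) {
    r <- c(min(col), max(col))
    if (diff(r) == 0) return(rep(mean(range), length(col)))
    (col - r[1]) / diff(r) * (range[2] - range[1]) + range[1]
  })
  items <- matrix(NA_real_, nrow(x), p * m)
  for (j in seq_len(p)) {
    for (i in seq_len(m)) {
      raw <- round(scaled[, j] + stats::rnorm(nrow(x), sd = noise_sd))
      items[, (j - 1L) * m + i] <- pmin(pmax(raw, range[1]), range[2])
    }
  }
  colnames(items) <- paste0(rep(colnames(x), each = m), "_it", rep(seq_len(m), p))
  scale_map <- stats::setNames(
    lapply(seq_len(p), function(j) (j - 1L) * m + seq_len(m)), colnames(x))
  likert_items(items, scale_map, range = range)
}

#' Write a machine- and human-readable run report
#'
#' Writes the results bundle of one analysis run into a directory with fixed
#' file names: \code{report.json} (config echo, QC tables, best models, MORI,
#' matches, seeds) plus TSVs for the QC table (\code{qc_table.tsv}), merge
#' table (\code{merges.tsv}), BIC table (\code{bic_table.tsv}) and MORI table
#' (\code{mori.tsv}) when the corresponding results are present.
#'
#' @param results named list; recognized elements: \code{config} (list),
#'   \code{qc_table} (data.frame), \code{dendro} (a \code{"dendro"}),
#'   \code{mbca} (an \code{"mbca_fit"}), \code{mori} (a
#'   \code{"mori_report"}), \code{matches} (data.frame), \code{seed}.
#' @param dir output directory (created if needed).
#' @return invisibly, the path of report.json.
#' @export
run_report <- function(results, dir) {
  if (!length(results)) stop("empty results bundle")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) stop("cannot create output directory ", dir)
  json <- list(package = "clustype",
               version = as.character(utils::packageVersion("clustype")),
               config = results$config, seed = results$seed)
  if (!is.null(results$qc_table)) {
    utils::write.table(results$qc_table, file.path(dir, "qc_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    json$qc_table <- results$qc_table
  }
  if (!is.null(results$dendro)) {
    export_merge_table(results$dendro, file.path(dir, "merges.tsv"))
  }
  if (!is.null(results$mbca)) {
    export_ic_tables(results$mbca, file.path(dir, "bic_table.tsv"),
                     file.path(dir, "icl_table.tsv"))
    json$best_by_bic <- results$mbca$best_by_bic[c("model", "k")]
    json$best_by_icl <- results$mbca$best_by_icl[c("model", "k")]
  }
  if (!is.null(results$mori)) {
    utils::write.table(results$mori$table, file.path(dir, "mori.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    json$mori <- results$mori$table
  }
  if (!is.null(results$matches)) json$matches <- results$matches
  path <- file.path(dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
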