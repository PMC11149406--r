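#' Likert item set
#'
#' Bundles an item-level response matrix with its scale map and per-scale
#' missing-item policy, the unit the scale-construction pipeline operates on.
#'
#' @param items numeric matrix (cases x items), NAs mark missing responses.
#' @param scale_map named list: scale name -> column indices or names.
#' @param range length-2 integer vector, the admissible item range.
#' @param max_missing named integer vector (or single integer recycled): how
#'   many missing items a scale tolerates before the scale score is set
#'   missing.
#' @return object of class \code{"likert_items"}.
#' @export
likert_items <- function(items, scale_map, range = c(1L, 5L), max_missing = 0L) {
  items <- as_data_matrix(items)
  if (!length(scale_map)) stop("scale_map must be nonempty")
  if (is.null(names(scale_map)) || any(names(scale_map) == "")) {
    stop("scale_map must be a named list")
  }
  scale_map <- lapply(scale_map, function(idx) {
    if (is.character(idx)) idx <- match(idx, colnames(items))
    if (anyNA(idx) || any(idx < 1L | idx > ncol(items))) stop("scale_map references unknown items")
    as.integer(idx)
  })
  ok <- items >= range[1] & items <= range[2]
  if (any(!ok[!is.na(items)])) stop("item values outside declared range")
  if (length(max_missing) == 1L) {
    max_missing <- stats::setNames(rep(as.integer(max_missing), length(scale_map)),
                                   names(scale_map))
  }
  structure(list(items = items, scale_map = scale_map, range = as.numeric(range),
                 max_missing = max_missing),
            class = "likert_items")
}

#' Truncate (cap) Likert items per scale
#'
#' Fuses the upper response categories of heavily right-skewed items: every
#' value above the cap is set to the cap (e.g. anxiety items capped at 3 fuse
#' the original responses 3, 4 and 5).  Missing entries are untouched and the
#' recorded item range is updated.
#'
#' @param x a \code{\link{likert_items}} object.
#' @param caps named numeric vector: scale name -> cap value.
#' @return a new \code{likert_items} object with capped values.
#' @export
truncate_items <- function(x, caps) {
  stopifnot(inherits(x, "likert_items"))
  unknown <- setdiff(names(caps), names(x$scale_map))
  if (length(unknown)) stop("caps reference unknown scales: ", paste(unknown, collapse = ", "))
  if (any(caps > x$range[2] | caps < x$range[1])) stop("cap outside item range")
  items <- x$items
  for (sc in names(caps)) {
    idx <- x$scale_map[[sc]]
    block <- items[, idx, drop = FALSE]
    block[!is.na(block) & block > caps[[sc]]] <- caps[[sc]]
    items[, idx] <- block
  }
  out <- x
  out$items <- items
  hi_per_scale <- vapply(names(x$scale_map), function(s) {
    if (s %in% names(caps)) caps[[s]] else x$range[2]
  }, numeric(1L))
  out$range <- c(x$range[1], max(hi_per_scale))
  out
}

#' Build scale scores from items
#'
#' The scale score is the mean of the non-missing items when the number of
#' missing items does not exceed the scale's missing-item allowance, and
#' missing otherwise (e.g. a 4-item anxiety scale with allowance 0 is missing
#' as soon as one item is missing; a 6-item avoidance scale with allowance 1
#' averages the 5 usable items).
#'
#' @param x a \code{\link{likert_items}} object.
#' @return numeric matrix (cases x scales) with NAs where the rule failed.
#' @export
build_scales <- function(x) {
  stopifnot(inherits(x, "likert_items"))
  out <- sapply(names(x$scale_map), function(sc) {
    block <- x$items[, x$scale_map[[sc]], drop = FALSE]
    nmiss <- rowSums(is.na(block))
    score <- rowMeans(block, na.rm = TRUE)
    score[nmiss > x$max_missing[[sc]]] <- NA_real_
    score[nmiss == ncol(block)] <- NA_real_
    score
  })
  out <- matrix(out, nrow = nrow(x$items),
                dimnames = list(rownames(x$items), names(x$scale_map)))
  if (any(colSums(!is.na(out)) == 0L)) stop("scale with zero usable cases")
  out
}

#' Keep cases complete on the given variables
#'
#' @param x numeric matrix or data frame.
#' @param vars variable names to require (default all).
#' @return matrix restricted to complete rows; the number dropped is reported
#'   via attribute \code{n_dropped}.
#' @export
complete_cases_on <- function(x, vars = NULL) {
  x <- as_data_matrix(x)
  if (is.null(vars)) vars <- colnames(x)
  miss <- setdiff(vars, colnames(x))
  if (length(miss)) stop("unknown variables: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(x[, vars, drop = FALSE])
  if (!any(keep)) stop("no complete cases remain")
  out <- x[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Nearest-neighbour ASED outlier screen
#'
#' For each case, the mean ASED to its \code{neighbours} nearest other cases
#' on the standardized variables; cases farther than \code{tau} from everyone
#' (default 0.7) are flagged as multivariate outliers.
#'
#' @param x standardized numeric matrix.
#' @param tau flagging threshold on the nearest-neighbour ASED (> 0).
#' @param neighbours how many nearest neighbours to average over (default 1).
#' @return data.frame with case, nn_ased, flagged; threshold in attribute
#'   \code{tau}.
#' @export
nn_outliers <- function(x, tau = 0.7, neighbours = 1L) {
  x <- as_data_matrix(x)
  if (!is_standardized(x)) warning("x does not look standardized; tau = 0.7 assumes z-scores")
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 cases")
  neighbours <- min(as.integer(neighbours), n - 1L)
  d <- pairwise_distances(x, "ased")
  diag(d) <- Inf
  nn <- apply(d, 1L, function(row) mean(sort(row, partial = neighbours)[seq_len(neighbours)]))
  out <- data.frame(case = rownames(x), nn_ased = nn, flagged = nn > tau,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "tau") <- tau
  out
}

# Cronbach alpha on a complete item matrix
cronbach_alpha <- function(block) {
  m <- ncol(block)
  v <- stats::var(rowSums(block))
  if (v <= 0) return(NA_real_)
  m / (m - 1) * (1 - sum(apply(block, 2L, stats::var)) / v)
}

# one-factor ML fit on the correlation matrix -> list(lambda, theta) or NULL
one_factor_fit <- function(block) {
  R <- stats::cor(block)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    if (all(abs(R - 1) < 1e-8)) {
      # exact duplicates: ML limit is a perfect single factor
      return(list(lambda = rep(1, ncol(block)), theta = rep(0, ncol(block))))
    }
    return(NULL)
  }
  fit <- tryCatch(stats::factanal(covmat = R, factors = 1L, n.obs = nrow(block)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  lambda <- as.numeric(fit$loadings)
  if (sum(lambda) < 0) lambda <- -lambda
  list(lambda = lambda, theta = fit$uniquenesses)
}

omega_from_fit <- function(fit) {
  s <- sum(fit$lambda)
  s^2 / (s^2 + sum(fit$theta))
}

#' Scale reliability: Cronbach's alpha and McDonald's omega
#'
#' Alpha uses the classical m/(m-1) * (1 - sum of item variances / total
#' variance) formula on the listwise-complete cases of each scale, with a
#' Feldt F-distribution confidence interval.  Omega-total comes from a
#' one-factor maximum-likelihood fit of the item correlation matrix,
#' omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta), with a seeded
#' percentile-bootstrap interval.  A non-convergent factor fit yields alpha
#' only, with a warning recorded in the report.
#'
#' @param x a \code{\link{likert_items}} object.
#' @param n_boot bootstrap replicates for the omega interval (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return data.frame, one row per scale: usable_cases, alpha, alpha_lo,
#'   alpha_hi, omega, omega_lo, omega_hi, warning.
#' @export
reliability <- function(x, n_boot = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(inherits(x, "likert_items"))
  a2 <- (1 - conf) / 2
  rows <- lapply(names(x$scale_map), function(sc) {
    block <- x$items[, x$scale_map[[sc]], drop = FALSE]
    block <- block[stats::complete.cases(block), , drop = FALSE]
    n <- nrow(block); m <- ncol(block)
    if (m < 2L) stop("scale ", sc, " has fewer than 2 items")
    if (n < 3L) stop("scale ", sc, " has fewer than 3 complete cases")
    alpha <- cronbach_alpha(block)
    # Feldt: (1 - alpha_hat)/(1 - alpha) ~ F(n-1, (n-1)(m-1))
    df1 <- n - 1; df2 <- (n - 1) * (m - 1)
    alo <- 1 - (1 - alpha) / stats::qf(a2, df1, df2)
    ahi <- 1 - (1 - alpha) / stats::qf(1 - a2, df1, df2)
    fit <- one_factor_fit(block)
    warn <- NA_character_
    omega <- olo <- ohi <- NA_real_
    if (is.null(fit)) {
      warn <- "one-factor ML fit did not converge; omega omitted"
    } else {
      omega <- omega_from_fit(fit)
      set.seed(seed)
      boots <- replicate(n_boot, {
        b <- block[sample.int(n, n, replace = TRUE), , drop = FALSE]
        f <- one_factor_fit(b)
        if (is.null(f)) NA_real_ else omega_from_fit(f)
      })
      boots <- boots[!is.na(boots)]
      if (length(boots) >= max(20L, n_boot / 2)) {
        q <- stats::quantile(boots, c(a2, 1 - a2), names = FALSE)
        olo <- q[1]; ohi <- q[2]
      } else {
        warn <- "omega bootstrap mostly non-convergent; interval omitted"
      }
    }
    data.frame(scale = sc, usable_cases = n, alpha = alpha,
               alpha_lo = min(alo, ahi), alpha_hi = max(alo, ahi),
               omega = omega, omega_lo = olo, omega_hi = ohi,
               warning = warn, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
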