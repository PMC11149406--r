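MODEL_NAMES <- c("EII", "VII", "EEI", "VEI", "EVI", "VVI", "EEE", "VEE",
                 "EVE", "VVE", "EEV", "VEV", "EVV", "VVV")

#' Free-parameter count of a Gaussian-mixture covariance model
#'
#' m = (k - 1) mixing weights + k*p means + the covariance parameters of the
#' volume/shape/orientation eigen-decomposition Sigma_c = lambda_c D_c A_c
#' D_c': volume contributes 1 (shared, E) or k (varying, V); shape 0 (I),
#' p - 1 (E) or k(p - 1) (V); orientation 0 (I), p(p-1)/2 (E) or
#' k*p(p-1)/2 (V).
#'
#' @param model one of the 14 model names ("EII" ... "VVV").
#' @param k number of mixture components.
#' @param p number of variables.
#' @return integer, the free-parameter count entering BIC.
#' @export
count_params <- function(model, k, p) {
  model <- match.arg(model, MODEL_NAMES)
  ch <- strsplit(model, "")[[1L]]
  vol <- if (ch[1] == "V") k else 1
  shape <- switch(ch[2], I = 0, E = p - 1, V = k * (p - 1))
  orient <- switch(ch[3], I = 0, E = p * (p - 1) / 2, V = k * p * (p - 1) / 2)
  as.integer((k - 1) + k * p + vol + shape + orient)
}

#' Fit one Gaussian mixture model by EM
#'
#' Maximum-likelihood EM fit of a single (model, k) cell through the mclust
#' engine, with its deterministic model-based hierarchical initialization.
#' BIC uses the larger-is-better convention 2*loglik - m*log(n); ICL = BIC -
#' 2 * classification entropy (so ICL <= BIC, with equality for 0/1
#' posteriors).  Covariance collapse or any other estimation failure marks
#' the cell non-converged instead of raising.
#'
#' @param x numeric data matrix.
#' @param model one of the 14 covariance parameterizations.
#' @param k number of components.
#' @param tol EM convergence tolerance on the relative loglik change.
#' @param max_iter EM iteration cap.
#' @return object of class \code{"gmm_fit"}: weights, means (p x k),
#'   covariances, loglik, n_params, bic, icl, z, converged.
#' @export
fit_gmm <- function(x, model, k, tol = 1e-6, max_iter = 500L) {
  model <- match.arg(model, MODEL_NAMES)
  x <- as_data_matrix(x)
  m <- count_params(model, k, ncol(x))
  if (nrow(x) <= m) warning("n <= free-parameter count; fit may be unstable")
  fit <- tryCatch(
    suppressWarnings(Mclust(x, G = k, modelNames = model, verbose = FALSE,
                            control = emControl(tol = c(tol, sqrt(tol)),
                                                itmax = c(max_iter, max_iter)))),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$loglik) || !is.finite(fit$loglik)) {
    return(structure(list(model = model, k = k, converged = FALSE,
                          n_params = m, bic = NA_real_, icl = NA_real_),
                     class = "gmm_fit"))
  }
  z <- fit$z
  if (is.null(z)) z <- matrix(1, nrow(x), 1L)
  ent <- entropy_of(z)
  bic <- 2 * fit$loglik - m * log(nrow(x))
  structure(list(model = model, k = k, converged = TRUE,
                 weights = fit$parameters$pro, means = fit$parameters$mean,
                 variance = fit$parameters$variance, loglik = fit$loglik,
                 n_params = m, bic = bic, icl = bic - 2 * ent, z = z,
                 n = nrow(x)),
            class = "gmm_fit")
}

entropy_of <- function(z) {
  zl <- z * log(z)
  zl[!is.finite(zl)] <- 0
  -sum(zl)
}

#' @export
print.gmm_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("Gaussian mixture %s, k = %d: did not converge\n", x$model, x$k))
  } else {
    cat(sprintf("Gaussian mixture %s, k = %d: loglik = %.3f, m = %d, BIC = %.2f, ICL = %.2f\n",
                x$model, x$k, x$loglik, x$n_params, x$bic, x$icl))
  }
  invisible(x)
}

#' Model-based cluster analysis over a model/k grid
#'
#' Fits every requested covariance model at every k (allowed range 2-25,
#' default 2-9), collects the BIC and ICL tables (non-converged cells stay
#' NA, mirroring gaps in a BIC plot), and selects the best cell under each
#' criterion, both on the larger-is-better scale.
#'
#' @param x numeric data matrix (standardization recommended).
#' @param models covariance model names (default all 14; duplicates dropped).
#' @param k_range integer vector of cluster numbers (default 2:9).
#' @return object of class \code{"mbca_fit"}: bic/icl matrices (rows = k),
#'   best_by_bic, best_by_icl (lists with model, k and the refitted
#'   \code{gmm_fit}), and the data dimensions.
#' @export
mbca <- function(x, models = MODEL_NAMES, k_range = 2:9) {
  x <- as_data_matrix(x)
  models <- unique(match.arg(models, MODEL_NAMES, several.ok = TRUE))
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > 25L)) stop("k_range must lie within 2..25")
  if (!is_standardized(x)) warning("x does not look standardized")
  bic <- icl <- matrix(NA_real_, length(k_range), length(models),
                       dimnames = list(k = k_range, model = models))
  fits <- vector("list", length(k_range) * length(models))
  dim(fits) <- dim(bic)
  for (j in seq_along(models)) {
    for (i in seq_along(k_range)) {
      f <- fit_gmm(x, models[j], k_range[i])
      fits[[i, j]] <- f
      if (f$converged) { bic[i, j] <- f$bic; icl[i, j] <- f$icl }
    }
  }
  if (all(is.na(bic))) stop("no (model, k) cell converged")
  best <- function(tab) {
    ij <- which(tab == max(tab, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    list(model = models[ij[2L]], k = k_range[ij[1L]], fit = fits[[ij[1L], ij[2L]]])
  }
  structure(list(bic = bic, icl = icl, best_by_bic = best(bic),
                 best_by_icl = best(icl), models = models, k_range = k_range,
                 n = nrow(x), p = ncol(x)),
            class = "mbca_fit")
}

#' @export
print.mbca_fit <- function(x, ...) {
  cat(sprintf("Model-based clustering over %d models x k in {%s}\n",
              length(x$models), paste(x$k_range, collapse = ", ")))
  cat(sprintf("  best by BIC: %s, k = %d (BIC = %.2f)\n", x$best_by_bic$model,
              x$best_by_bic$k, x$best_by_bic$fit$bic))
  cat(sprintf("  best by ICL: %s, k = %d (ICL = %.2f)\n", x$best_by_icl$model,
              x$best_by_icl$k, x$best_by_icl$fit$icl))
  nc <- sum(is.na(x$bic))
  if (nc) cat(sprintf("  %d non-converged cell(s)\n", nc))
  invisible(x)
}

#' Classify cases from a fitted mixture
#'
#' Hard labels by the maximum-posterior rule (ties to the lowest cluster
#' index) with per-case uncertainty u_i = 1 - max_c z_ic, which lies in
#' [0, 1 - 1/k].
#'
#' @param fit a converged \code{\link{fit_gmm}} object.
#' @return list: \code{labels} (1..k by first appearance kept as posterior
#'   column order), \code{uncertainty}.
#' @export
classify <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (!fit$converged) stop("model did not converge")
  labels <- max.col(fit$z, ties.method = "first")
  list(labels = labels, uncertainty = 1 - fit$z[cbind(seq_len(nrow(fit$z)), labels)])
}

#' Export BIC/ICL tables as TSV
#'
#' @param fit an \code{"mbca_fit"}.
#' @param path_bic,path_icl output files (NULL skips).
#' @export
export_ic_tables <- function(fit, path_bic = NULL, path_icl = NULL) {
  stopifnot(inherits(fit, "mbca_fit"))
  wr <- function(tab, path) {
    df <- data.frame(k = rownames(tab), tab, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  if (!is.null(path_bic)) wr(fit$bic, path_bic)
  if (!is.null(path_icl)) wr(fit$icl, path_icl)
  invisible(fit)
}
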