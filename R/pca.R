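#' Fit a PCA projection selected by cumulative variance ratio
#'
#' Centers the feature matrix, eigendecomposes its (sample, N-1 divisor)
#' covariance matrix, and retains the smallest number l of leading components
#' whose cumulative eigenvalue share reaches the threshold \code{w}:
#' \deqn{l = \min \{ l : \sum_{i \le l} \lambda_i / \sum_{i \le k} \lambda_i \ge w \}}
#' Each retained eigenvector is sign-normalised so that its largest-magnitude
#' coordinate is positive, making fitted models reproducible across runs and
#' platforms.
#'
#' @param x numeric matrix (rows = samples) or a \code{"dacc_features"}
#'   object.
#' @param w cumulative variance ratio in (0, 1]; default 0.99.
#' @return an object of class \code{"dacc_pca"}: \code{mean} (per-feature
#'   centering vector), \code{components} (k x l orthonormal matrix),
#'   \code{eigenvalues} (all min(n-1, k) eigenvalues, non-increasing),
#'   \code{l_retained}, \code{k_original}, \code{w_threshold}.
#' @export
fit_pca <- function(x, w = 0.99) {
  if (inherits(x, "dacc_features")) x <- x$x
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA requires at least 2 rows", call. = FALSE)
  if (length(w) != 1L || !is.finite(w) || w <= 0 || w > 1) {
    stop("w must be in (0, 1]", call. = FALSE)
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  total <- sum(ev)
  if (total <= 0) {
    stop("zero-variance matrix: all columns are constant", call. = FALSE)
  }
  ratio <- cumsum(ev) / total
  ratio[length(ratio)] <- 1  # guard cumsum/sum rounding at the top
  l <- which(ratio >= w - 1e-12)[1L]
  comp <- pr$rotation[, seq_len(l), drop = FALSE]
  # deterministic sign: largest-|coordinate| entry of each component positive
  flip <- vapply(seq_len(l), function(j) {
    v <- comp[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1L))
  comp <- sweep(comp, 2L, flip, "*")
  colnames(comp) <- paste0("PC", seq_len(l))
  structure(list(mean = pr$center,
                 components = comp,
                 eigenvalues = ev,
                 l_retained = l,
                 k_original = ncol(x),
                 w_threshold = w),
            class = "dacc_pca")
}

#' Project a feature matrix onto a fitted PCA subspace
#'
#' @param model a \code{"dacc_pca"} object from \code{\link{fit_pca}}.
#' @param x numeric matrix (or \code{"dacc_features"}) with the same number
#'   of columns the model was fitted on.
#' @return score matrix with \code{l_retained} columns named PC1..PCl.
#' @export
pca_transform <- function(model, x) {
  if (inherits(x, "dacc_features")) x <- x$x
  x <- as.matrix(x)
  if (ncol(x) != model$k_original) {
    stop(sprintf("dimension mismatch: matrix has %d columns, model expects %d",
                 ncol(x), model$k_original), call. = FALSE)
  }
  sweep(x, 2L, model$mean, "-") %*% model$components
}

#' @export
predict.dacc_pca <- function(object, newdata, ...) {
  pca_transform(object, newdata)
}

#' @export
print.dacc_pca <- function(x, ...) {
  cat(sprintf("PCA projection: %d -> %d dimensions (w = %g, %.1f%% variance retained)\n",
              x$k_original, x$l_retained, x$w_threshold,
              100 * sum(x$eigenvalues[seq_len(x$l_retained)]) / sum(x$eigenvalues)))
  invisible(x)
}

#' Export a PCA model to CSV for audit
#'
#' Writes the centering vector and the retained components as a plain-text
#' table (first row = mean vector, remaining rows = components).
#'
#' @param model a \code{"dacc_pca"} object.
#' @param path output CSV path.
#' @export
write_pca_csv <- function(model, path) {
  out <- rbind(mean = model$mean, t(model$components))
  utils::write.csv(out, path, row.names = TRUE)
  invisible(path)
}
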