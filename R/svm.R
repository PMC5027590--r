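#' RBF-SVM hyperparameter configuration
#'
#' Defaults are the operating point used throughout the package: C = 2^3 and
#' gamma = 2^-3.
#'
#' @param C regularisation parameter (> 0).
#' @param gamma RBF kernel width, k(x, y) = exp(-gamma * ||x - y||^2).
#' @return an object of class \code{"svm_config"}.
#' @export
svm_config <- function(C = 8, gamma = 0.125) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("C must be a positive number", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a positive number", call. = FALSE)
  }
  structure(list(C = C, gamma = gamma), class = "svm_config")
}

# dense RBF kernel between row sets
.rbf_kernel <- function(x, y, gamma) {
  sx <- rowSums(x^2)
  sy <- rowSums(y^2)
  d2 <- outer(sx, sy, "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0  # numerical guard
  exp(-gamma * d2)
}

# squared-distance matrix of a row set (for precomputed-kernel protocols)
.sqdist <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

.check_training_labels <- function(labels, n) {
  if (is.null(labels)) stop("labels are required for training", call. = FALSE)
  labels <- .match_labels(unname(as.character(labels)), ids = NULL, n = n)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training data must contain both classes (hot and cold)",
         call. = FALSE)
  }
  labels
}

# Solve the C-SVC problem on a precomputed training kernel. Returns the
# support-vector indices (into the training rows), sign-normalised dual
# coefficients A_i = alpha_i * y_i with hotspot = +1, and the offset rho such
# that decision = K[new, sv] %*% coefs - rho.
.train_kernel <- function(K, labels, config) {
  y <- .check_training_labels(labels, nrow(K))
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                     kernel = "matrix", C = config$C, tol = 1e-4)
  idx <- unlist(kernlab::SVindex(m))
  co <- unlist(kernlab::coef(m))
  rho <- kernlab::b(m)
  d0 <- as.vector(K[, idx, drop = FALSE] %*% co) - rho
  flip <- if (mean(d0[y == "hot"]) >= mean(d0[y == "cold"])) 1 else -1
  list(idx = idx, coefs = flip * co, rho = flip * rho)
}

#' Train the RBF-SVM hot/cold classifier
#'
#' Fits a C-SVC with RBF kernel on a feature matrix. The fit is
#' deterministic given the inputs; the decision-value sign is normalised so
#' that the hotspot class is positive, and the stored dual coefficients
#' A_i = alpha_i * y_i follow the same convention (y = +1 for hotspots).
#'
#' @param x numeric feature matrix (rows = samples) or a
#'   \code{"dacc_features"} object carrying labels.
#' @param labels class labels (\code{"hot"}/\code{"cold"}); taken from
#'   \code{x} when it is a \code{"dacc_features"} object.
#' @param config an \code{\link{svm_config}}.
#' @return an object of class \code{"dacc_svm"} with elements \code{sv}
#'   (support-vector matrix), \code{coefs} (signed dual coefficients of the
#'   support vectors), \code{rho} (offset), \code{alpha_full} (length-n
#'   vector of A_i over all training rows, zero off the support set),
#'   \code{C}, \code{gamma}, \code{n_train}, \code{feature_names}.
#' @export
train_classifier <- function(x, labels = NULL, config = svm_config()) {
  if (inherits(x, "dacc_features")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  y <- .check_training_labels(labels, nrow(x))
  K <- exp(-config$gamma * .sqdist(x))
  fit <- .train_kernel(K, y, config)
  alpha_full <- numeric(nrow(x))
  alpha_full[fit$idx] <- fit$coefs
  structure(list(sv = x[fit$idx, , drop = FALSE],
                 coefs = fit$coefs,
                 rho = fit$rho,
                 alpha_full = alpha_full,
                 sv_index = fit$idx,
                 C = config$C,
                 gamma = config$gamma,
                 n_train = nrow(x),
                 feature_names = colnames(x)),
            class = "dacc_svm")
}

#' Decision values and labels for new samples
#'
#' The predicted label is the sign of the decision value; a decision value
#' of exactly zero resolves to the hotspot class.
#'
#' @param object a \code{"dacc_svm"} model.
#' @param newdata numeric matrix (or \code{"dacc_features"}) with the same
#'   feature dimension the model was trained on.
#' @param ... unused.
#' @return a data.frame with columns \code{predicted} (factor hot/cold) and
#'   \code{decision}.
#' @export
predict.dacc_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "dacc_features")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$sv)) {
    stop(sprintf("dimension mismatch: input has %d features, model expects %d",
                 ncol(newdata), ncol(object$sv)), call. = FALSE)
  }
  d <- as.vector(.rbf_kernel(newdata, object$sv, object$gamma) %*%
                   object$coefs) - object$rho
  data.frame(predicted = factor(ifelse(d >= 0, "hot", "cold"),
                                levels = c("hot", "cold")),
             decision = d,
             row.names = rownames(newdata))
}

#' @export
print.dacc_svm <- function(x, ...) {
  cat(sprintf("RBF-SVM classifier: %d support vectors of %d samples (C = %g, gamma = %g)\n",
              length(x$coefs), x$n_train, x$C, x$gamma))
  invisible(x)
}

#' Default log2 hyperparameter grid
#'
#' log2 C in [-5, 15] and log2 gamma in [-15, 3], step 2; this grid contains
#' the default operating point (C = 8, gamma = 0.125).
#'
#' @return data.frame with columns \code{C} and \code{gamma}.
#' @export
default_svm_grid <- function() {
  g <- expand.grid(log2C = seq(-5, 15, by = 2),
                   log2gamma = seq(-15, 3, by = 2))
  data.frame(C = 2^g$log2C, gamma = 2^g$log2gamma)
}

#' Grid search for (C, gamma) by cross-validated accuracy
#'
#' Evaluates every grid point by stratified k-fold cross-validation on the
#' given matrix (SVM only; apply any PCA reduction beforehand) and returns
#' the pair with the highest mean accuracy. Ties are broken toward the
#' simpler model: smaller C first, then smaller gamma.
#'
#' @param x feature matrix or \code{"dacc_features"}.
#' @param labels class labels (from \code{x} if omitted).
#' @param grid data.frame with columns \code{C}, \code{gamma}; default
#'   \code{\link{default_svm_grid}}.
#' @param folds number of CV folds (>= 2).
#' @param seed seed for the fold assignment shuffle.
#' @return the winning \code{\link{svm_config}}, with the full accuracy
#'   table in attribute \code{"table"} and the seed in attribute
#'   \code{"seed"}.
#' @export
grid_search_svm <- function(x, labels = NULL, grid = default_svm_grid(),
                            folds = 5L, seed = 1L) {
  if (inherits(x, "dacc_features")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  y <- .check_training_labels(labels, nrow(x))
  if (nrow(grid) < 1L) stop("grid must be nonempty", call. = FALSE)
  fold_sets <- .stratified_folds(y, as.integer(folds), seed)
  D2 <- .sqdist(x)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- svm_config(C = grid$C[g], gamma = grid$gamma[g])
    K <- exp(-cfg$gamma * D2)
    correct <- 0L
    for (test in fold_sets) {
      train <- setdiff(seq_len(nrow(x)), test)
      fit <- .train_kernel(K[train, train, drop = FALSE], y[train], cfg)
      d <- as.vector(K[test, train[fit$idx], drop = FALSE] %*% fit$coefs) -
        fit$rho
      pred <- ifelse(d >= 0, "hot", "cold")
      correct <- correct + sum(pred == as.character(y[test]))
    }
    acc[g] <- correct / nrow(x)
  }
  ord <- order(-acc, grid$C, grid$gamma)
  best <- ord[1L]
  out <- svm_config(C = grid$C[best], gamma = grid$gamma[best])
  attr(out, "table") <- cbind(grid, accuracy = acc)
  attr(out, "seed") <- seed
  out
}

#' Discriminative weight vector of a trained SVM
#'
#' Computes the per-feature score W_j = sum_i A_i * M_ij, where M is the
#' training feature matrix and A_i is the signed dual coefficient of sample
#' i (alpha_i * y_i for support vectors, 0 otherwise, y = +1 for hotspots).
#' This is a pseudo-linear readout of an RBF model: it is the weight vector
#' the fitted coefficients would induce under a linear kernel, used to rank
#' features by discriminative power, not the true RBF decision gradient.
#' Features are ranked by |W_j| (descending); the sign of W_j is retained in
#' the output.
#'
#' @param model a \code{"dacc_svm"} trained on \code{x} (same rows, same
#'   order).
#' @param x the training feature matrix or \code{"dacc_features"} object the
#'   model was fitted on.
#' @return a data.frame with one row per feature: \code{feature},
#'   \code{mu1}, \code{mu2}, \code{lag} (parsed from DACC feature names when
#'   available, otherwise NA), \code{weight}, \code{abs_weight} and
#'   \code{rank} (1 = largest |W|).
#' @export
discriminative_weights <- function(model, x) {
  info <- NULL
  if (inherits(x, "dacc_features")) {
    info <- feature_info(x$config)
    x <- x$x
  }
  x <- as.matrix(x)
  if (nrow(x) != model$n_train) {
    stop(sprintf("matrix has %d rows but the model was trained on %d samples",
                 nrow(x), model$n_train), call. = FALSE)
  }
  if (ncol(x) != ncol(model$sv)) {
    stop("dimension mismatch between matrix and model", call. = FALSE)
  }
  w <- as.vector(crossprod(x, model$alpha_full))
  out <- data.frame(feature = colnames(x) %||% paste0("f", seq_along(w)),
                    mu1 = NA_character_, mu2 = NA_character_,
                    lag = NA_integer_, weight = w, abs_weight = abs(w),
                    stringsAsFactors = FALSE)
  if (!is.null(info) && identical(info$name, out$feature)) {
    out$mu1 <- info$mu1
    out$mu2 <- info$mu2
    out$lag <- info$lag
  }
  out$rank <- rank(-out$abs_weight, ties.method = "min")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export discriminative weights as CSV
#'
#' Writes the weight table sorted by rank (columns: feature, mu1, mu2, lag,
#' weight, abs_weight, rank).
#'
#' @param weights output of \code{\link{discriminative_weights}}.
#' @param path output CSV path.
#' @export
write_weights_csv <- function(weights, path) {
  utils::write.csv(weights[order(weights$rank), ], path, row.names = FALSE)
  invisible(path)
}
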