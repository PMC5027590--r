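#' Binary classification metrics from confusion counts
#'
#' Computes sensitivity Se = TP/(TP+FN), specificity Sp = TN/(TN+FP),
#' accuracy Acc = (TP+TN)/total and the Matthews correlation coefficient
#' \deqn{Mcc = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' When any factor of the Mcc denominator is zero the coefficient is defined
#' as 0 (the conventional completion of the formula).
#'
#' @param counts a named numeric vector or list with elements \code{TP},
#'   \code{FP}, \code{TN}, \code{FN} (nonnegative, total > 0).
#' @return a list with elements \code{Se}, \code{Sp}, \code{Acc},
#'   \code{Mcc}.
#' @examples
#' classification_metrics(c(TP = 10, FP = 0, TN = 10, FN = 0))
#' @export
classification_metrics <- function(counts) {
  cn <- c("TP", "FP", "TN", "FN")
  if (!all(cn %in% names(counts))) {
    stop("counts must have named elements TP, FP, TN, FN", call. = FALSE)
  }
  v <- vapply(cn, function(k) as.numeric(counts[[k]]), numeric(1L))
  if (any(v < 0)) stop("confusion counts must be nonnegative", call. = FALSE)
  tp <- v[["TP"]]; fp <- v[["FP"]]; tn <- v[["TN"]]; fn <- v[["FN"]]
  total <- tp + fp + tn + fn
  if (total <= 0) stop("confusion counts sum to zero", call. = FALSE)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(Se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       Sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       Acc = (tp + tn) / total,
       Mcc = if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0)
}

# counts from truth/predicted factors (hot = positive class)
.confusion_counts <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  c(TP = sum(truth == "hot" & predicted == "hot"),
    FP = sum(truth == "cold" & predicted == "hot"),
    TN = sum(truth == "cold" & predicted == "cold"),
    FN = sum(truth == "hot" & predicted == "cold"))
}

# stratified fold assignment from a seeded shuffle; returns a list of test
# index vectors covering 1..n exactly once
.stratified_folds <- function(labels, k, seed) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  idx_by_class <- split(seq_along(labels), labels)
  if (any(vapply(idx_by_class, length, integer(1L)) < k)) {
    stop(sprintf("k = %d exceeds the size of the smallest class (%d)", k,
                 min(vapply(idx_by_class, length, integer(1L)))),
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  folds <- vector("list", k)
  for (cls_idx in idx_by_class) {
    shuffled <- sample(cls_idx)
    assign_to <- rep_len(seq_len(k), length(shuffled))
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], shuffled[assign_to == f])
    }
  }
  lapply(folds, sort)
}

# Core fold engine: refits the configured pipeline (optional PCA + RBF-SVM)
# on each training set and predicts the held-out rows. When reduction is
# disabled the full RBF kernel is precomputed once -- kernel entries depend
# only on pairs of encoded sequences, never on training statistics, so this
# is leakage-free and each fold still solves its own SVM on the training
# submatrix.
.evaluate_folds <- function(x, y, config, fold_sets) {
  n <- nrow(x)
  all_test <- unlist(fold_sets)
  stopifnot(length(all_test) == n, identical(sort(all_test), seq_len(n)))
  svm_cfg <- svm_config(C = config$C, gamma = config$gamma)
  pred <- character(n)
  dec <- numeric(n)
  if (!config$reduce) {
    K <- exp(-svm_cfg$gamma * .sqdist(x))
    for (test in fold_sets) {
      train <- setdiff(seq_len(n), test)
      stopifnot(length(intersect(train, test)) == 0L)  # leakage guard
      fit <- .train_kernel(K[train, train, drop = FALSE], y[train], svm_cfg)
      d <- as.vector(K[test, train[fit$idx], drop = FALSE] %*% fit$coefs) -
        fit$rho
      pred[test] <- ifelse(d >= 0, "hot", "cold")
      dec[test] <- d
    }
  } else {
    for (test in fold_sets) {
      train <- setdiff(seq_len(n), test)
      stopifnot(length(intersect(train, test)) == 0L)  # leakage guard
      pca <- fit_pca(x[train, , drop = FALSE], w = config$w)
      xt <- pca_transform(pca, x[train, , drop = FALSE])
      model <- train_classifier(xt, y[train], svm_cfg)
      p <- predict(model, pca_transform(pca, x[test, , drop = FALSE]))
      pred[test] <- as.character(p$predicted)
      dec[test] <- p$decision
    }
  }
  list(predicted = factor(pred, levels = c("hot", "cold")), decision = dec)
}

.as_labeled_matrix <- function(features, labels) {
  if (inherits(features, "dacc_features")) {
    if (is.null(labels)) labels <- features$labels
    x <- features$x
  } else {
    x <- as.matrix(features)
  }
  if (is.null(labels)) stop("labels are required for evaluation", call. = FALSE)
  labels <- .match_labels(unname(as.character(labels)), NULL, nrow(x))
  list(x = x, y = labels)
}

.make_eval_result <- function(protocol, k, seed, y, res, ids) {
  counts <- .confusion_counts(y, res$predicted)
  structure(list(protocol = protocol, k = k, seed = seed,
                 counts = counts,
                 metrics = classification_metrics(counts),
                 predictions = data.frame(
                   id = ids %||% seq_along(y),
                   truth = y, predicted = res$predicted,
                   decision = res$decision,
                   stringsAsFactors = FALSE)),
            class = "recspot_eval")
}

#' Jackknife (leave-one-out) evaluation of the pipeline
#'
#' Every sequence is held out exactly once; the configured pipeline (PCA
#' reduction if enabled, then the RBF-SVM) is refitted on the remaining
#' samples and used to predict the held-out sample. Feature encoding is
#' sequence-local, so it is computed once up front without leakage.
#'
#' @param features a \code{"dacc_features"} object (encoded sequences with
#'   labels) or a plain feature matrix.
#' @param config a \code{\link{pipeline_config}}.
#' @param labels class labels if \code{features} is a plain matrix.
#' @param fast_pca if \code{TRUE} and reduction is enabled, a single PCA is
#'   fitted on the full dataset and reused across folds. This leaks the
#'   held-out sample into the projection and is provided only to probe how
#'   much that leakage matters; a warning is always emitted.
#' @return an object of class \code{"recspot_eval"} with confusion counts,
#'   Se/Sp/Acc/Mcc and the per-sample predictions.
#' @export
jackknife_eval <- function(features, config = pipeline_config(),
                           labels = NULL, fast_pca = FALSE) {
  dat <- .as_labeled_matrix(features, labels)
  if (min(table(dat$y)) < 2L) {
    stop("jackknife requires at least 2 samples per class", call. = FALSE)
  }
  x <- dat$x
  cfg <- config
  if (cfg$reduce && fast_pca) {
    warning("fast_pca = TRUE reuses one full-data PCA across folds; ",
            "the held-out sample leaks into the projection", call. = FALSE)
    x <- pca_transform(fit_pca(x, w = cfg$w), x)
    cfg$reduce <- FALSE
  }
  fold_sets <- as.list(seq_len(nrow(x)))
  res <- .evaluate_folds(x, dat$y, cfg, fold_sets)
  .make_eval_result("jackknife", NA_integer_, NA_integer_, dat$y, res,
                    rownames(dat$x))
}

#' Stratified k-fold evaluation of the pipeline
#'
#' @inheritParams jackknife_eval
#' @param k number of folds (>= 2, at most the smallest class size). The
#'   limiting case k = n is accepted and evaluated as singleton folds, i.e.
#'   the jackknife.
#' @param seed seed for the stratified fold-assignment shuffle.
#' @return an object of class \code{"recspot_eval"}.
#' @export
kfold_eval <- function(features, k = 5L, seed = 1L,
                       config = pipeline_config(), labels = NULL) {
  dat <- .as_labeled_matrix(features, labels)
  k <- as.integer(k)
  fold_sets <- if (k == length(dat$y)) as.list(seq_along(dat$y)) else
    .stratified_folds(dat$y, k, seed)
  res <- .evaluate_folds(dat$x, dat$y, config, fold_sets)
  .make_eval_result("kfold", as.integer(k), as.integer(seed), dat$y, res,
                    rownames(dat$x))
}

#' Accuracy as a function of the maximum lag
#'
#' Re-encodes the sequences at each candidate LAG and evaluates the pipeline
#' by stratified k-fold cross-validation with a fixed seed, so the accuracy
#' values are comparable across lags.
#'
#' @param sequences named character vector of DNA sequences.
#' @param labels class labels (\code{"hot"}/\code{"cold"}).
#' @param lags integer vector of maximum-lag values to try.
#' @param config a \code{\link{pipeline_config}}; its \code{lag} field is
#'   overridden by each sweep value.
#' @param k,seed cross-validation folds and shuffle seed (shared across
#'   lags).
#' @return a data.frame with columns \code{lag} and \code{Acc}.
#' @export
lag_sweep <- function(sequences, labels, lags, config = pipeline_config(),
                      k = 5L, seed = 1L) {
  lags <- as.integer(lags)
  if (length(lags) < 1L || any(is.na(lags) | lags < 1L)) {
    stop("lags must be positive integers", call. = FALSE)
  }
  acc <- vapply(lags, function(lg) {
    cfg <- config
    cfg$lag <- lg
    feats <- encode_batch(sequences, labels, encoding_config(
      lag = lg, properties = config$properties,
      standardize = config$standardize))
    kfold_eval(feats, k = k, seed = seed, config = cfg)$metrics$Acc
  }, numeric(1L))
  data.frame(lag = lags, Acc = acc)
}

#' @export
print.recspot_eval <- function(x, ...) {
  proto <- if (x$protocol == "kfold")
    sprintf("%d-fold CV (seed %d)", x$k, x$seed) else x$protocol
  cat("Evaluation:", proto, "on", sum(x$counts), "samples\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              x$counts[["TP"]], x$counts[["FP"]],
              x$counts[["TN"]], x$counts[["FN"]]))
  cat(sprintf("  Se %.4f  Sp %.4f  Acc %.4f  Mcc %.4f\n",
              x$metrics$Se, x$metrics$Sp, x$metrics$Acc, x$metrics$Mcc))
  invisible(x)
}
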