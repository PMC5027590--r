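#' Full pipeline configuration
#'
#' Collects every tunable of the hot/cold-spot pipeline with defaults at the
#' standard operating point: LAG = 6, raw property values, PCA reduction at
#' cumulative variance ratio w = 0.99, and an RBF-SVM with C = 2^3 and
#' gamma = 2^-3.
#'
#' @param lag maximum lag for the DACC encoding.
#' @param standardize z-score property rows before encoding.
#' @param reduce apply PCA reduction before the SVM.
#' @param w cumulative variance ratio for component selection.
#' @param C,gamma RBF-SVM hyperparameters.
#' @param properties property table (default: the 15 shipped properties).
#' @return an object of class \code{"recspot_config"}.
#' @export
pipeline_config <- function(lag = 6L, standardize = FALSE, reduce = TRUE,
                            w = 0.99, C = 8, gamma = 0.125,
                            properties = property_table()) {
  enc <- encoding_config(lag = lag, properties = properties,
                         standardize = standardize)
  svm <- svm_config(C = C, gamma = gamma)
  if (!is.numeric(w) || length(w) != 1L || w <= 0 || w > 1) {
    stop("w must be in (0, 1]", call. = FALSE)
  }
  structure(list(lag = enc$lag, standardize = standardize,
                 reduce = isTRUE(reduce), w = w, C = svm$C,
                 gamma = svm$gamma, properties = enc$properties),
            class = "recspot_config")
}

#' @export
print.recspot_config <- function(x, ...) {
  cat(sprintf("Pipeline: LAG = %d, properties %s, PCA %s, SVM C = %g gamma = %g\n",
              x$lag, if (x$standardize) "standardized" else "raw",
              if (x$reduce) sprintf("w = %g", x$w) else "disabled",
              x$C, x$gamma))
  invisible(x)
}

.encoding_from_pipeline <- function(config) {
  encoding_config(lag = config$lag, properties = config$properties,
                  standardize = config$standardize)
}

#' Fit the full hot/cold-spot pipeline
#'
#' Encodes the sequences (unless pre-encoded features are given), optionally
#' fits the PCA reduction, and trains the RBF-SVM on the (reduced) feature
#' matrix.
#'
#' @param sequences named character vector of DNA sequences, or a
#'   \code{"dacc_features"} object from \code{\link{encode_batch}}.
#' @param labels class labels (\code{"hot"}/\code{"cold"}); taken from the
#'   features object if omitted.
#' @param config a \code{\link{pipeline_config}}.
#' @return an object of class \code{"recspot_model"} bundling the encoding
#'   configuration, the fitted PCA model (or \code{NULL}), the SVM and the
#'   label convention (hotspot = positive).
#' @export
fit_recspot <- function(sequences, labels = NULL,
                        config = pipeline_config()) {
  feats <- if (inherits(sequences, "dacc_features")) sequences else
    encode_batch(sequences, labels, .encoding_from_pipeline(config))
  if (is.null(labels)) labels <- feats$labels
  x <- feats$x
  pca <- NULL
  if (config$reduce) {
    pca <- fit_pca(x, w = config$w)
    x <- pca_transform(pca, x)
  }
  svm <- train_classifier(x, labels,
                          svm_config(C = config$C, gamma = config$gamma))
  structure(list(config = config, pca = pca, svm = svm,
                 positive_class = "hot",
                 version = as.character(utils::packageVersion("daccspot"))),
            class = "recspot_model")
}

#' Predict hot/cold labels for new sequences
#'
#' @param object a \code{"recspot_model"} from \code{\link{fit_recspot}}.
#' @param sequences named character vector of DNA sequences or a
#'   \code{"dacc_features"} object encoded with the model's configuration.
#' @param ... unused.
#' @return a data.frame with columns \code{id}, \code{predicted} and
#'   \code{decision} (positive = hotspot).
#' @export
predict.recspot_model <- function(object, sequences, ...) {
  feats <- if (inherits(sequences, "dacc_features")) sequences else
    encode_batch(sequences, labels = NULL,
                 .encoding_from_pipeline(object$config))
  x <- feats$x
  if (!is.null(object$pca)) x <- pca_transform(object$pca, x)
  p <- predict(object$svm, x)
  data.frame(id = rownames(feats$x), predicted = p$predicted,
             decision = p$decision, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @export
print.recspot_model <- function(x, ...) {
  cat("Recombination-spot classifier\n")
  print(x$config)
  if (!is.null(x$pca)) print(x$pca)
  print(x$svm)
  invisible(x)
}

#' Save / load a fitted model archive
#'
#' The archive is a single RDS file bundling the encoding configuration, the
#' PCA model (if any), the SVM state and the package version.
#'
#' @param model a \code{"recspot_model"}.
#' @param path archive path.
#' @return \code{save_recspot} returns the path invisibly;
#'   \code{load_recspot} returns the model.
#' @export
save_recspot <- function(model, path) {
  stopifnot(inherits(model, "recspot_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_recspot
#' @export
load_recspot <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path,
                               call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "recspot_model")) {
    stop("file is not a recspot model archive", call. = FALSE)
  }
  model
}
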