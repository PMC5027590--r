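#' Encoding configuration for DACC features
#'
#' Bundles the maximum lag, the property table and the standardisation flag
#' used by the covariance encoders. With the default 15 properties and
#' \code{lag = 6} the DAC block has 15 x 6 = 90 features, the DCC block
#' 15 x 14 x 6 = 1260, and the concatenated DACC vector 1350.
#'
#' @param lag maximum dinucleotide offset LAG (features are emitted for every
#'   lag 1..LAG). Default 6.
#' @param properties a property table (see \code{\link{property_table}});
#'   must have at least 2 properties for the cross-covariance block.
#' @param standardize z-score the property rows before encoding.
#' @return an object of class \code{"dacc_config"}.
#' @export
encoding_config <- function(lag = 6L, properties = property_table(),
                            standardize = FALSE) {
  lag <- as.integer(lag)
  if (length(lag) != 1L || is.na(lag) || lag < 1L) {
    stop("lag must be a positive integer", call. = FALSE)
  }
  if (nrow(properties) < 2L) {
    stop("at least 2 properties are required (DCC needs ordered pairs)",
         call. = FALSE)
  }
  if (standardize && !isTRUE(attr(properties, "standardized"))) {
    properties <- standardize_properties(properties)
  }
  structure(list(lag = lag, properties = properties,
                 standardize = standardize),
            class = "dacc_config")
}

#' @export
print.dacc_config <- function(x, ...) {
  n <- nrow(x$properties)
  cat("DACC encoding config:", n, "properties, LAG =", x$lag,
      if (x$standardize) "(standardized)" else "(raw)", "\n")
  cat("  DAC", n * x$lag, "+ DCC", n * (n - 1L) * x$lag,
      "=", n * x$lag * n, "features\n")
  invisible(x)
}

# validate and uppercase a DNA sequence; reports 1-based offending positions
.check_sequence <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  s <- toupper(sequence)
  bad <- gregexpr("[^ACGT]", s)[[1L]]
  if (bad[1L] != -1L) {
    stop(sprintf("invalid character '%s' at position %d (only A/C/G/T allowed)",
                 substr(s, bad[1L], bad[1L]), bad[1L]), call. = FALSE)
  }
  if (nchar(s) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  s
}

# (L-1) x N matrix of property values along the dinucleotide positions
.profile_matrix <- function(sequence, properties) {
  L <- nchar(sequence)
  b <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  dinucs <- paste0(b[-L], b[-1L])
  idx <- .dinuc_class_index[dinucs]
  # properties is N x 10; take its transpose rows by class index
  t(properties)[idx, , drop = FALSE]
}

#' Property profile of a sequence
#'
#' Maps a DNA sequence to the series of property values of its overlapping
#' dinucleotides: element i (1-based, i = 1..L-1) is the value of property
#' \code{property} for the dinucleotide at positions i..i+1.
#'
#' @param sequence a DNA string (A/C/G/T, case-insensitive), length L >= 2.
#' @param property a property name.
#' @param config an \code{\link{encoding_config}}.
#' @return a list with \code{values} (numeric, length L-1) and \code{mean}
#'   (the profile average used for centering in the covariance encoders).
#' @examples
#' dinucleotide_profile("ACGT", "F-roll")   # 0.06 0.04 0.06
#' @export
dinucleotide_profile <- function(sequence, property,
                                 config = encoding_config()) {
  s <- .check_sequence(sequence)
  if (!property %in% rownames(config$properties)) {
    stop("unknown property name: ", property, call. = FALSE)
  }
  p <- .profile_matrix(s, config$properties)[, property]
  list(values = unname(p), mean = mean(p))
}

# shared precondition for covariance terms at a given lag
.check_lag_length <- function(L, lag) {
  if (L < lag + 2L) {
    stop(sprintf("sequence too short: length %d < %d (need L >= lag + 2 for lag %d)",
                 L, lag + 2L, lag), call. = FALSE)
  }
}

#' Dinucleotide auto covariance at a single lag
#'
#' The covariance of one property's dinucleotide profile with itself at a
#' positional offset \code{lag}:
#' \deqn{DAC(\mu, lag) = \sum_{i=1}^{L-1-lag} (P_\mu(i) - \bar P_\mu)(P_\mu(i+lag) - \bar P_\mu) / (L - 1 - lag)}
#' with \eqn{\bar P_\mu} the profile mean over all L-1 positions.
#'
#' @inheritParams dinucleotide_profile
#' @param lag positive integer offset; requires L >= lag + 2.
#' @return a single covariance value.
#' @export
dac <- function(sequence, property, lag, config = encoding_config()) {
  s <- .check_sequence(sequence)
  lag <- as.integer(lag)
  .check_lag_length(nchar(s), lag)
  pr <- dinucleotide_profile(s, property, config)
  d <- pr$values - pr$mean
  m <- length(d)
  sum(d[seq_len(m - lag)] * d[seq_len(m - lag) + lag]) / (m - lag)
}

#' Dinucleotide cross covariance at a single lag
#'
#' The covariance between two different properties' profiles at offset
#' \code{lag}: position i of \code{property1} against position i + lag of
#' \code{property2}. Pairs are ordered, so \code{dcc(s, p1, p2, lag)} and
#' \code{dcc(s, p2, p1, lag)} are distinct features.
#'
#' @inheritParams dac
#' @param property1,property2 two different property names.
#' @return a single covariance value.
#' @export
dcc <- function(sequence, property1, property2, lag,
                config = encoding_config()) {
  if (identical(property1, property2)) {
    stop("property1 and property2 must differ; use dac() for auto covariance",
         call. = FALSE)
  }
  s <- .check_sequence(sequence)
  lag <- as.integer(lag)
  .check_lag_length(nchar(s), lag)
  p1 <- dinucleotide_profile(s, property1, config)
  p2 <- dinucleotide_profile(s, property2, config)
  d1 <- p1$values - p1$mean
  d2 <- p2$values - p2$mean
  m <- length(d1)
  sum(d1[seq_len(m - lag)] * d2[seq_len(m - lag) + lag]) / (m - lag)
}

#' Canonical feature metadata for a configuration
#'
#' @param config an \code{\link{encoding_config}}.
#' @return a data.frame with columns \code{name}, \code{block}
#'   (\code{"DAC"}/\code{"DCC"}), \code{mu1}, \code{mu2} (\code{NA} for DAC)
#'   and \code{lag}, one row per feature in canonical order: the DAC block
#'   (property outer, lag inner) followed by the DCC block (ordered property
#'   pairs outer, lag inner).
#' @export
feature_info <- function(config = encoding_config()) {
  props <- rownames(config$properties)
  n <- length(props)
  lags <- seq_len(config$lag)
  dac_df <- data.frame(
    block = "DAC",
    mu1 = rep(props, each = config$lag),
    mu2 = NA_character_,
    lag = rep(lags, times = n),
    stringsAsFactors = FALSE
  )
  pairs <- expand.grid(mu2 = props, mu1 = props, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$mu1 != pairs$mu2, c("mu1", "mu2")]
  # expand.grid varies mu2 fastest; reorder so mu1 is the outer loop in
  # table order, mu2 the middle loop
  pairs <- pairs[order(match(pairs$mu1, props), match(pairs$mu2, props)), ]
  dcc_df <- data.frame(
    block = "DCC",
    mu1 = rep(pairs$mu1, each = config$lag),
    mu2 = rep(pairs$mu2, each = config$lag),
    lag = rep(lags, times = nrow(pairs)),
    stringsAsFactors = FALSE
  )
  out <- rbind(dac_df, dcc_df)
  out$name <- ifelse(out$block == "DAC",
                     sprintf("DAC(%s,%d)", out$mu1, out$lag),
                     sprintf("DCC(%s,%s,%d)", out$mu1, out$mu2, out$lag))
  rownames(out) <- NULL
  out[, c("name", "block", "mu1", "mu2", "lag")]
}

#' Encode one sequence as a DACC feature vector
#'
#' Concatenates the auto-covariance (DAC) block and the cross-covariance
#' (DCC) block for every lag 1..LAG, in the canonical order of
#' \code{\link{feature_info}}.
#'
#' @inheritParams dinucleotide_profile
#' @return a named numeric vector of length N*LAG + N*(N-1)*LAG.
#' @examples
#' v <- encode_dacc(paste(rep("ACGT", 5), collapse = ""))
#' length(v)  # 1350 with the default 15 properties and LAG = 6
#' @export
encode_dacc <- function(sequence, config = encoding_config()) {
  s <- .check_sequence(sequence)
  .check_lag_length(nchar(s), config$lag)
  P <- .profile_matrix(s, config$properties)
  n <- ncol(P)
  m <- nrow(P)
  Pc <- sweep(P, 2L, colMeans(P), "-")
  # cov_arr[mu1, mu2, lag] = sum_i Pc[i, mu1] * Pc[i + lag, mu2] / (m - lag)
  cov_arr <- array(0, dim = c(n, n, config$lag))
  for (lg in seq_len(config$lag)) {
    head_rows <- seq_len(m - lg)
    cov_arr[, , lg] <- crossprod(Pc[head_rows, , drop = FALSE],
                                 Pc[head_rows + lg, , drop = FALSE]) / (m - lg)
  }
  # vapply gives an n x LAG matrix; t() + as.vector walks lag within mu
  dac_block <- as.vector(t(vapply(seq_len(config$lag),
                                  function(lg) diag(cov_arr[, , lg]),
                                  numeric(n))))
  dcc_block <- numeric(n * (n - 1L) * config$lag)
  k <- 0L
  for (mu1 in seq_len(n)) {
    for (mu2 in seq_len(n)) {
      if (mu1 == mu2) next
      dcc_block[k + seq_len(config$lag)] <- cov_arr[mu1, mu2, ]
      k <- k + config$lag
    }
  }
  out <- c(dac_block, dcc_block)
  names(out) <- feature_info(config)$name
  out
}

#' Encode a batch of sequences into a feature matrix
#'
#' @param sequences named character vector of DNA sequences (names are
#'   record ids) or a \code{Biostrings::DNAStringSet}.
#' @param labels optional factor/character of class labels (\code{"hot"} /
#'   \code{"cold"}), one per sequence, or a named vector matched to sequence
#'   ids.
#' @param config an \code{\link{encoding_config}}.
#' @param skip_invalid if \code{TRUE}, sequences that fail encoding (e.g.
#'   ambiguity codes, too short) are dropped with a recorded reason instead
#'   of failing the batch.
#' @return an object of class \code{"dacc_features"}: a list with \code{x}
#'   (rows = sequences, columns = named features), \code{labels} (factor with
#'   levels \code{hot}, \code{cold}, or \code{NULL}), \code{config} and
#'   \code{skipped} (data.frame of id/reason for dropped records).
#' @export
encode_batch <- function(sequences, labels = NULL,
                         config = encoding_config(), skip_invalid = FALSE) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0L) {
    stop("empty input: no sequences to encode", call. = FALSE)
  }
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("seq_%04d", seq_along(sequences))
  labels <- .match_labels(labels, ids, length(sequences))
  rows <- vector("list", length(sequences))
  errs <- character(length(sequences))
  for (i in seq_along(sequences)) {
    # rows[i] <- list(...) so a NULL marks failure instead of dropping the slot
    rows[i] <- list(tryCatch(encode_dacc(sequences[[i]], config),
                             error = function(e) {
                               errs[i] <<- conditionMessage(e)
                               NULL
                             }))
  }
  failed <- vapply(rows, is.null, logical(1L))
  if (any(failed) && !skip_invalid) {
    msg <- paste(sprintf("  %s: %s", ids[failed], errs[failed]),
                 collapse = "\n")
    stop("encoding failed for ", sum(failed), " record(s):\n", msg,
         call. = FALSE)
  }
  skipped <- data.frame(id = ids[failed], reason = errs[failed],
                        stringsAsFactors = FALSE)
  keep <- !failed
  if (!any(keep)) stop("all records failed encoding", call. = FALSE)
  x <- do.call(rbind, rows[keep])
  rownames(x) <- ids[keep]
  structure(list(x = x,
                 labels = if (is.null(labels)) NULL else labels[keep],
                 config = config, skipped = skipped),
            class = "dacc_features")
}

# normalise labels to a factor with levels hot (positive) / cold
.match_labels <- function(labels, ids, n) {
  if (is.null(labels)) return(NULL)
  if (!is.null(names(labels))) {
    miss <- setdiff(ids, names(labels))
    if (length(miss)) {
      stop("labels missing for id(s): ", paste(utils::head(miss, 5L),
                                               collapse = ", "), call. = FALSE)
    }
    labels <- labels[ids]
  } else if (length(labels) != n) {
    stop("labels must have one entry per sequence", call. = FALSE)
  }
  labels <- as.character(labels)
  bad <- !labels %in% c("hot", "cold")
  if (any(bad)) {
    stop("labels must be 'hot' or 'cold'; got: ",
         paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
  }
  factor(labels, levels = c("hot", "cold"))
}

#' @export
print.dacc_features <- function(x, ...) {
  cat("DACC feature matrix:", nrow(x$x), "sequences x", ncol(x$x),
      "features\n")
  if (!is.null(x$labels)) {
    cat("  labels:", sum(x$labels == "hot"), "hot /",
        sum(x$labels == "cold"), "cold\n")
  }
  if (nrow(x$skipped)) cat("  skipped:", nrow(x$skipped), "record(s)\n")
  invisible(x)
}
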