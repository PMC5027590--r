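#' Read a multi-FASTA file of DNA sequences
#'
#' Handles wrapped sequence lines and CRLF line endings. Record ids are the
#' first whitespace-delimited token of each header (the remainder of the
#' header is kept in the \code{"description"} attribute); duplicate ids and
#' empty records are rejected.
#'
#' @param path path to a FASTA file.
#' @param full_names keep the complete header line as the record id instead
#'   of the first token.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, full_names = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("FASTA parse error in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- as.character(set)
  headers <- names(set)
  ids <- if (full_names) headers else sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path,
                              call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ",
         paste(utils::head(ids[empty], 5L), collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  attr(seqs, "description") <- sub("^\\S*\\s?", "", headers)
  seqs
}

#' Write sequences to a multi-FASTA file
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width for the sequence lines.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", ids[i]), con)
    s <- sequences[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a two-column label table
#'
#' @param path TSV with columns \code{id} and \code{label} (hot/cold);
#'   a header line is optional.
#' @return named factor of labels (levels hot, cold) keyed by id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("id", "label"))
  if (identical(tolower(df$id[1L]), "id")) df <- df[-1L, , drop = FALSE]
  bad <- !df$label %in% c("hot", "cold")
  if (any(bad)) {
    stop("labels must be 'hot' or 'cold'; offending id(s): ",
         paste(utils::head(df$id[bad], 5L), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate ids in label file: ",
         paste(utils::head(unique(df$id[duplicated(df$id)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  stats::setNames(factor(df$label, levels = c("hot", "cold")), df$id)
}

#' Write labels as a two-column TSV
#'
#' @param labels named factor/character of hot/cold labels.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(id = names(labels),
                                label = as.character(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Load sequences from separate positive and negative FASTA files
#'
#' @param pos_path FASTA of hotspot (positive) sequences.
#' @param neg_path FASTA of coldspot (negative) sequences.
#' @return list with \code{sequences} (named character) and \code{labels}
#'   (named factor).
#' @export
read_two_class_fasta <- function(pos_path, neg_path) {
  pos <- read_fasta(pos_path)
  neg <- read_fasta(neg_path)
  both <- intersect(names(pos), names(neg))
  if (length(both)) {
    stop("id(s) present in both classes: ",
         paste(utils::head(both, 5L), collapse = ", "), call. = FALSE)
  }
  seqs <- c(pos, neg)
  labels <- stats::setNames(
    factor(rep(c("hot", "cold"), c(length(pos), length(neg))),
           levels = c("hot", "cold")), names(seqs))
  list(sequences = seqs, labels = labels)
}

#' Write a feature matrix as CSV
#'
#' Columns are the named features; an optional leading \code{label} column
#' carries the class.
#'
#' @param features a \code{"dacc_features"} object or numeric matrix.
#' @param path output path.
#' @param labels optional labels when \code{features} is a plain matrix.
#' @export
write_feature_csv <- function(features, path, labels = NULL) {
  if (inherits(features, "dacc_features")) {
    if (is.null(labels)) labels <- features$labels
    x <- features$x
  } else {
    x <- as.matrix(features)
  }
  df <- as.data.frame(x, check.names = FALSE)
  if (!is.null(labels)) df <- cbind(label = as.character(labels), df)
  utils::write.csv(cbind(id = rownames(x), df), path, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix in sparse LIBSVM text format
#'
#' One line per sample: \code{<label> <index>:<value> ...} with 1-based
#' feature indices, zeros omitted, and labels encoded +1 (hot) / -1 (cold).
#'
#' @param features a \code{"dacc_features"} object or numeric matrix.
#' @param path output path.
#' @param labels labels when \code{features} is a plain matrix.
#' @export
write_libsvm <- function(features, path, labels = NULL) {
  if (inherits(features, "dacc_features")) {
    if (is.null(labels)) labels <- features$labels
    x <- features$x
  } else {
    x <- as.matrix(features)
  }
  if (is.null(labels)) stop("labels are required for LIBSVM output",
                            call. = FALSE)
  y <- ifelse(as.character(labels) == "hot", "+1", "-1")
  lines <- vapply(seq_len(nrow(x)), function(i) {
    nz <- which(x[i, ] != 0)
    paste(y[i], paste(sprintf("%d:%.10g", nz, x[i, nz]), collapse = " "))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' The report embeds the protocol descriptor, the confusion counts, the
#' Se/Sp/Acc/Mcc metrics and, optionally, the fully resolved pipeline
#' configuration for provenance.
#'
#' @param result a \code{"recspot_eval"} object.
#' @param path output path.
#' @param config optional \code{\link{pipeline_config}} to embed.
#' @export
write_evaluation_json <- function(result, path, config = NULL) {
  stopifnot(inherits(result, "recspot_eval"))
  payload <- list(
    protocol = result$protocol,
    k = if (is.na(result$k)) NULL else result$k,
    seed = if (is.na(result$seed)) NULL else result$seed,
    counts = as.list(result$counts),
    metrics = result$metrics,
    n = sum(result$counts)
  )
  if (!is.null(config)) {
    payload$config <- list(lag = config$lag, standardize = config$standardize,
                           reduce = config$reduce, w = config$w,
                           C = config$C, gamma = config$gamma)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write per-sample predictions as TSV
#'
#' Columns: id, true label (if known), predicted label, decision value.
#'
#' @param predictions the \code{predictions} data.frame of a
#'   \code{"recspot_eval"}, or the output of
#'   \code{\link{predict.recspot_model}}.
#' @param path output path.
#' @export
write_predictions_tsv <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
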