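# Canonical strand-symmetric dinucleotide classes, in the column order of the
# shipped property table.
DINUC_CLASSES <- c("AA/TT", "AC/GT", "AG/CT", "AT", "CA/TG",
                   "CC/GG", "CG", "GA/TC", "GC", "TA")

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a dinucleotide
#'
#' @param dinuc character vector of 2-mers over A/C/G/T.
#' @return character vector of reverse-complemented 2-mers.
#' @examples
#' revcomp_dinucleotide(c("AA", "AC", "CG"))
#' @export
revcomp_dinucleotide <- function(dinuc) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b1 <- substr(dinuc, 1L, 1L)
  b2 <- substr(dinuc, 2L, 2L)
  paste0(comp[b2], comp[b1])
}

#' Strand-symmetric class of a dinucleotide
#'
#' Each of the 16 dinucleotides maps to one of 10 classes; a dinucleotide and
#' its reverse complement always share a class (a double-stranded base-pair
#' step is the same physical object read from either strand).
#'
#' @param dinuc character vector of 2-mers over A/C/G/T (case-insensitive).
#' @return character vector of class labels, e.g. \code{"AC/GT"}.
#' @examples
#' dinucleotide_class(c("GT", "TT", "CG"))
#' @export
dinucleotide_class <- function(dinuc) {
  dinuc <- toupper(dinuc)
  bad <- !grepl("^[ACGT]{2}$", dinuc)
  if (any(bad)) {
    stop("invalid dinucleotide(s): ", paste(unique(dinuc[bad]), collapse = ", "),
         " (only A/C/G/T 2-mers are allowed)", call. = FALSE)
  }
  rc <- revcomp_dinucleotide(dinuc)
  # class label is "d/rc" with d the lexicographically smaller member,
  # collapsed to a single token for self-complementary dinucleotides
  lo <- pmin(dinuc, rc)
  hi <- pmax(dinuc, rc)
  ifelse(lo == hi, lo, paste0(lo, "/", hi))
}

# 16-element lookup: dinucleotide -> column index into the 10-class table
.dinuc_class_index <- local({
  all16 <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  idx <- match(dinucleotide_class(all16), DINUC_CLASSES)
  names(idx) <- all16
  idx
})

#' Dinucleotide physicochemical property table
#'
#' Loads the table of 15 dinucleotide physicochemical properties (flexibility
#' parameters F-roll..F-rise, the static geometry parameters roll..rise and
#' the thermodynamic parameters energy, enthalpy, entropy) over the 10
#' strand-symmetric dinucleotide classes. A user-supplied CSV of the same
#' shape (property name column plus the 10 class columns) may be given for
#' custom property sets.
#'
#' @param path optional path to a CSV with a \code{property} column followed
#'   by the 10 class columns \code{AA/TT, AC/GT, ..., TA}. \code{NULL} loads
#'   the table shipped with the package.
#' @param standardize if \code{TRUE}, each property row is z-scored across
#'   the 10 classes (see \code{\link{standardize_properties}}). Default keeps
#'   the raw published values.
#' @return a numeric matrix (properties x 10 classes) of class
#'   \code{"dinuc_property_table"}, with property names as row names and
#'   class labels as column names.
#' @examples
#' tab <- property_table()
#' dim(tab)  # 15 x 10
#' @export
property_table <- function(path = NULL, standardize = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "dinucleotide_properties.csv",
                        package = "daccspot", mustWork = TRUE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"property" %in% names(df)) {
    stop("property CSV must have a 'property' column", call. = FALSE)
  }
  if (!setequal(setdiff(names(df), "property"), DINUC_CLASSES)) {
    stop("property CSV must have exactly the 10 class columns: ",
         paste(DINUC_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$property)) {
    stop("duplicated property names in CSV", call. = FALSE)
  }
  if (nrow(df) < 1L) stop("property CSV has no property rows", call. = FALSE)
  m <- as.matrix(df[, DINUC_CLASSES, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) {
    stop("property CSV contains non-numeric or missing values", call. = FALSE)
  }
  rownames(m) <- df$property
  class(m) <- c("dinuc_property_table", class(m))
  if (standardize) m <- standardize_properties(m)
  m
}

#' Look up a property value for a dinucleotide
#'
#' @param property property name (a row name of \code{table}).
#' @param dinucleotide a 2-mer over A/C/G/T; strand-symmetric, so e.g.
#'   \code{"TT"} resolves to the \code{"AA/TT"} class.
#' @param table a property table from \code{\link{property_table}}.
#' @return the scalar property value (vectorised over
#'   \code{property}/\code{dinucleotide} of equal length).
#' @examples
#' property_value("F-slide", "AT")   # 9.61
#' property_value("entropy", "CG")   # -27.20
#' @export
property_value <- function(property, dinucleotide, table = property_table()) {
  ri <- match(property, rownames(table))
  if (anyNA(ri)) {
    stop("unknown property name(s): ",
         paste(unique(property[is.na(ri)]), collapse = ", "), call. = FALSE)
  }
  ci <- .dinuc_class_index[toupper(dinucleotide)]
  if (anyNA(ci)) {
    stop("invalid dinucleotide(s): ",
         paste(unique(dinucleotide[is.na(ci)]), collapse = ", "),
         " (only A/C/G/T are allowed)", call. = FALSE)
  }
  table[cbind(ri, unname(ci))]
}

#' Z-score each property row across the 10 dinucleotide classes
#'
#' Transforms every property so that its 10 class values have zero mean and
#' unit standard deviation. Standardisation puts all properties on a common
#' scale before covariance encoding; the default pipeline keeps the raw
#' published values.
#'
#' @param table a property table from \code{\link{property_table}}.
#' @return a standardized \code{"dinuc_property_table"}.
#' @export
standardize_properties <- function(table) {
  mu <- rowMeans(table)
  sdv <- apply(table, 1L, stats::sd)
  if (any(sdv <= 0)) {
    stop("degenerate property (zero variance across classes): ",
         paste(rownames(table)[sdv <= 0], collapse = ", "), call. = FALSE)
  }
  out <- (table - mu) / sdv
  class(out) <- c("dinuc_property_table", setdiff(class(out), "dinuc_property_table"))
  attr(out, "standardized") <- TRUE
  out
}
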