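#' Specification for a synthetic two-class sequence set
#'
#' Describes a labeled benchmark of hotspot-like positives and coldspot-like
#' negatives with a controllable, covariance-detectable class difference.
#' Negatives are i.i.d. uniform A/C/G/T. Positives are drawn from a lag-
#' factorised copy chain: nucleotide j copies nucleotide j - signal_lag with
#' probability \code{effect_size} (and is uniform otherwise), which is a
#' first-order Markov chain within each residue class modulo the lag. The
#' copying correlates successive dinucleotides at the planted offset and so
#' inflates the lag-\code{signal_lag} autocovariance of every dinucleotide
#' property while leaving single-nucleotide composition uniform;
#' \code{signal_property} designates the feature tracked by downstream
#' checks. At \code{effect_size = 0} the two classes are exchangeable.
#'
#' @param n_pos,n_neg number of positive (hot) and negative (cold) records.
#' @param length_range integer vector of length 2: min/max sequence length,
#'   sampled uniformly; the minimum must be at least \code{signal_lag + 2}.
#' @param signal_property property whose planted-lag autocovariance feature
#'   is tracked by the tests.
#' @param signal_lag offset (in dinucleotide positions) at which the class
#'   signal is planted.
#' @param effect_size copy probability in [0, 1); 0 gives exchangeable
#'   classes.
#' @param seed integer seed; all generator randomness flows from it.
#' @return an object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_pos = 100L, n_neg = 100L,
                           length_range = c(200L, 600L),
                           signal_property = "F-rise", signal_lag = 3L,
                           effect_size = 0.3, seed = 1L) {
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  signal_lag <- as.integer(signal_lag)
  length_range <- as.integer(length_range)
  if (n_pos < 1L || n_neg < 1L) stop("class sizes must be >= 1", call. = FALSE)
  if (length(length_range) != 2L || any(is.na(length_range)) ||
      length_range[1L] > length_range[2L]) {
    stop("length_range must be c(min, max) with min <= max", call. = FALSE)
  }
  if (signal_lag < 1L) stop("signal_lag must be >= 1", call. = FALSE)
  if (length_range[1L] < signal_lag + 2L) {
    stop(sprintf("minimum length %d is too short for signal_lag %d (need >= %d)",
                 length_range[1L], signal_lag, signal_lag + 2L), call. = FALSE)
  }
  if (!is.numeric(effect_size) || effect_size < 0 || effect_size >= 1) {
    stop("effect_size must be in [0, 1)", call. = FALSE)
  }
  if (!signal_property %in% rownames(property_table())) {
    stop("unknown signal_property: ", signal_property, call. = FALSE)
  }
  structure(list(n_pos = n_pos, n_neg = n_neg, length_range = length_range,
                 signal_property = signal_property, signal_lag = signal_lag,
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# one sequence from the lag-ell copy chain with persistence p;
# base letters are uniform, and each position j > ell copies x[j - ell]
# with probability p. Vectorised via a "last fresh draw" index per chain.
.copy_chain_sequence <- function(L, ell, p) {
  z <- sample(DNA_BASES, L, replace = TRUE)
  if (p <= 0 || L <= ell) return(paste(z, collapse = ""))
  copy <- stats::runif(L) < p
  copy[seq_len(min(ell, L))] <- FALSE  # chain heads are always fresh
  x <- character(L)
  for (r in seq_len(ell)) {
    pos <- seq.int(r, L, by = ell)
    fresh <- !copy[pos]
    src <- cummax(ifelse(fresh, seq_along(pos), 0L))
    x[pos] <- z[pos[src]]
  }
  paste(x, collapse = "")
}

#' Generate a labeled synthetic sequence set
#'
#' Fully reproducible from the seed in \code{spec}; the caller's RNG state
#' is left untouched.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a list of class \code{"recspot_simulation"} with \code{sequences}
#'   (named character vector; headers carry class and generation metadata),
#'   \code{labels} (factor hot/cold, in record order) and \code{spec}.
#' @examples
#' sim <- simulate_recspots(synthetic_spec(n_pos = 5, n_neg = 5, seed = 42))
#' table(sim$labels)
#' @export
simulate_recspots <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
          else if (exists(".Random.seed", envir = .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(spec$seed)
  n <- spec$n_pos + spec$n_neg
  # sample.int avoids the sample() scalar pitfall when min == max
  span <- spec$length_range[2L] - spec$length_range[1L] + 1L
  lens <- spec$length_range[1L] + sample.int(span, n, replace = TRUE) - 1L
  labels <- factor(rep(c("hot", "cold"), c(spec$n_pos, spec$n_neg)),
                   levels = c("hot", "cold"))
  seqs <- character(n)
  for (i in seq_len(n)) {
    p <- if (labels[i] == "hot") spec$effect_size else 0
    seqs[i] <- .copy_chain_sequence(lens[i], spec$signal_lag, p)
  }
  names(seqs) <- sprintf("%s_%04d class=%s lag=%d effect=%g seed=%d",
                         ifelse(labels == "hot", "hot", "cold"),
                         seq_len(n), labels, spec$signal_lag,
                         ifelse(labels == "hot", spec$effect_size, 0),
                         spec$seed)
  structure(list(sequences = seqs, labels = labels, spec = spec),
            class = "recspot_simulation")
}

#' Benchmark-shaped synthetic set (490 hotspots + 591 coldspots)
#'
#' Convenience preset matching the class sizes of the standard yeast
#' recombination benchmark, for full-protocol rehearsal without external
#' data.
#'
#' @param seed generator seed.
#' @param effect_size planted copy-chain persistence (see
#'   \code{\link{synthetic_spec}}).
#' @param ... further arguments passed to \code{\link{synthetic_spec}}.
#' @return a \code{"recspot_simulation"} with 490 positives and 591
#'   negatives.
#' @export
simulate_benchmark <- function(seed = 1L, effect_size = 0.3, ...) {
  simulate_recspots(synthetic_spec(n_pos = 490L, n_neg = 591L,
                                   effect_size = effect_size, seed = seed,
                                   ...))
}

#' @export
print.recspot_simulation <- function(x, ...) {
  cat(sprintf("Synthetic set: %d hot + %d cold sequences (lengths %d-%d, lag %d, effect %g, seed %d)\n",
              x$spec$n_pos, x$spec$n_neg, x$spec$length_range[1L],
              x$spec$length_range[2L], x$spec$signal_lag,
              x$spec$effect_size, x$spec$seed))
  invisible(x)
}
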