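# Independent brute-force transcriptions of the covariance definitions and
# small shared fixtures. The oracles deliberately avoid the package's
# vectorised code paths: profiles are built by per-position lookup and the
# covariance sums by explicit indexing.

# per-position property profile by direct table lookup
oracle_profile <- function(sequence, property, tab) {
  s <- toupper(sequence)
  L <- nchar(s)
  vapply(seq_len(L - 1L), function(i) {
    property_value(property, substr(s, i, i + 1L), tab)
  }, numeric(1L))
}

# auto covariance: explicit sum over i of centered products
oracle_dac <- function(sequence, property, lag, tab) {
  p <- oracle_profile(sequence, property, tab)
  pbar <- mean(p)
  m <- length(p)
  total <- 0
  for (i in seq_len(m - lag)) {
    total <- total + (p[i] - pbar) * (p[i + lag] - pbar)
  }
  total / (m - lag)
}

# cross covariance: property1 at i against property2 at i + lag
oracle_dcc <- function(sequence, p1, p2, lag, tab) {
  a <- oracle_profile(sequence, p1, tab)
  b <- oracle_profile(sequence, p2, tab)
  abar <- mean(a); bbar <- mean(b)
  m <- length(a)
  total <- 0
  for (i in seq_len(m - lag)) {
    total <- total + (a[i] - abar) * (b[i + lag] - bbar)
  }
  total / (m - lag)
}

# full DACC vector in canonical order, assembled feature by feature
oracle_encode <- function(sequence, config) {
  tab <- config$properties
  info <- feature_info(config)
  vapply(seq_len(nrow(info)), function(j) {
    if (info$block[j] == "DAC") {
      oracle_dac(sequence, info$mu1[j], info$lag[j], tab)
    } else {
      oracle_dcc(sequence, info$mu1[j], info$mu2[j], info$lag[j], tab)
    }
  }, numeric(1L))
}

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# separable two-cluster fixture for classifier tests
make_clusters <- function(n_per = 50L, k = 5L, shift = 4, seed = 7L) {
  set.seed(seed)
  x <- matrix(rnorm(2L * n_per * k), 2L * n_per, k)
  x[seq_len(n_per), 1L] <- x[seq_len(n_per), 1L] + shift
  colnames(x) <- paste0("f", seq_len(k))
  list(x = x,
       y = factor(rep(c("hot", "cold"), each = n_per),
                  levels = c("hot", "cold")))
}
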