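# Per-feature indexed-sum transcription of the covariance definitions,
# independent of the package's centered-crossprod implementation but fast
# enough for long random-sequence sweeps.
oracle_encode_fast <- function(sequence, config) {
  tab <- config$properties
  props <- rownames(tab)
  profiles <- vapply(props, function(p) oracle_profile(sequence, p, tab),
                     numeric(nchar(sequence) - 1L))
  means <- colMeans(profiles)
  m <- nrow(profiles)
  info <- feature_info(config)
  vapply(seq_len(nrow(info)), function(j) {
    lg <- info$lag[j]
    a <- profiles[, info$mu1[j]] - means[info$mu1[j]]
    b_name <- if (info$block[j] == "DAC") info$mu1[j] else info$mu2[j]
    b <- profiles[, b_name] - means[b_name]
    sum(a[seq_len(m - lg)] * b[seq_len(m - lg) + lg]) / (m - lg)
  }, numeric(1L))
}
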