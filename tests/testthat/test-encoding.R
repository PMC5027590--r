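test_that("dinucleotide profiles match direct table lookups", {
  pr <- dinucleotide_profile("ACGT", "F-roll")
  expect_equal(pr$values, c(0.06, 0.04, 0.06))
  expect_equal(pr$mean, 0.16 / 3)
  expect_equal(dinucleotide_profile("ACGT", "F-tilt")$values,
               c(0.07, 0.06, 0.07))
  # homogeneous dinucleotide content gives a constant profile
  expect_equal(dinucleotide_profile("AAAA", "F-slide")$values,
               rep(6.69, 3))
  # lower-case input is accepted
  expect_equal(dinucleotide_profile("acgt", "F-roll")$values,
               c(0.06, 0.04, 0.06))
})

test_that("single-lag covariances reproduce hand-computed toy values", {
  # profiles for "ACGT": F-roll (0.06, 0.04, 0.06), F-tilt (0.07, 0.06, 0.07);
  # two centered products each, denominator L - 1 - lag = 2
  expect_equal(dac("ACGT", "F-roll", 1), -8.888889e-05, tolerance = 1e-6)
  expect_equal(dcc("ACGT", "F-roll", "F-tilt", 1), -4.444444e-05,
               tolerance = 1e-6)
  # homopolymers have zero deviation from the profile mean at every lag
  for (lg in 1:6) expect_identical(dac("AAAAAAAA", "F-roll", lg), 0)
  expect_identical(dcc("AAAAAAAA", "twist", "rise", 3), 0)
})

test_that("a single-summand covariance equals the product of two deviations", {
  set.seed(4)
  for (rep in 1:5) {
    s <- random_dna(6L)   # L - 1 - lag = 1 at lag 4
    p <- dinucleotide_profile(s, "twist")
    d <- p$values - p$mean
    expect_equal(dac(s, "twist", 4), d[1] * d[5])
  }
})

test_that("covariance operations validate their inputs", {
  expect_error(dac("ACG", "F-roll", 2), "too short")
  expect_error(dac("ACGNT", "F-roll", 1), "position 4")
  expect_error(dcc("ACGTACGT", "F-roll", "F-roll", 1), "must differ")
  expect_error(dinucleotide_profile("ACGT", "nope"), "unknown property")
  expect_error(encode_dacc("ACGTA", encoding_config(lag = 6)), "too short")
})

test_that("DACC dimension law holds over a grid of N and LAG", {
  tab <- property_table()
  for (n in c(2L, 3L, 5L, 15L)) {
    sub <- tab[seq_len(n), , drop = FALSE]
    for (lg in c(1L, 2L, 6L)) {
      cfg <- encoding_config(lag = lg, properties = sub)
      v <- encode_dacc(strrep("ACGT", 10L), cfg)
      expect_length(v, n * lg + n * (n - 1L) * lg)
      info <- feature_info(cfg)
      expect_equal(sum(info$block == "DAC"), n * lg)
      expect_equal(sum(info$block == "DCC"), n * (n - 1L) * lg)
      expect_identical(names(v), info$name)
    }
  }
  # canonical default: 90 DAC + 1260 DCC = 1350
  v <- encode_dacc(strrep("ACGT", 10L))
  expect_length(v, 1350L)
  expect_true(all(startsWith(names(v)[1:90], "DAC(")))
  expect_true(all(startsWith(names(v)[91:1350], "DCC(")))
})

test_that("the vectorised encoder matches the brute-force oracle", {
  set.seed(11)
  # full 15-property encoder on a spread of lengths
  cfg <- encoding_config(lag = 4)
  for (L in c(10L, 37L, 120L)) {
    s <- random_dna(L)
    expect_equal(unname(encode_dacc(s, cfg)), oracle_encode(s, cfg),
                 tolerance = 1e-12)
  }
  # small-N configs, scalar-loop oracle
  cfg3 <- encoding_config(lag = 3, properties = property_table()[c(2, 6, 13), ])
  for (rep in 1:10) {
    s <- random_dna(sample(10:60, 1L))
    expect_equal(unname(encode_dacc(s, cfg3)), oracle_encode(s, cfg3),
                 tolerance = 1e-12)
  }
})

test_that("standardized-property encoding uses the z-scored table", {
  s <- random_dna(50L)
  cfg_std <- encoding_config(lag = 2, standardize = TRUE)
  cfg_pre <- encoding_config(lag = 2,
                             properties = standardize_properties(property_table()))
  expect_equal(encode_dacc(s, cfg_std), encode_dacc(s, cfg_pre))
})

test_that("expected DAC of i.i.d. uniform sequences vanishes at long lengths", {
  set.seed(21)
  reps <- 40L
  vals <- vapply(seq_len(reps), function(i) {
    dac(random_dna(10000L), "twist", 3)
  }, numeric(1L))
  se <- sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals)), 4 * se + 1e-8)
})

test_that("batch encoding preserves order, labels and skip semantics", {
  set.seed(5)
  seqs <- setNames(vapply(1:3, function(i) random_dna(40L), character(1L)),
                   c("a", "b", "c"))
  labels <- c(a = "hot", b = "cold", c = "hot")
  f <- encode_batch(seqs, labels, encoding_config(lag = 2))
  expect_equal(rownames(f$x), c("a", "b", "c"))
  expect_equal(as.character(f$labels), c("hot", "cold", "hot"))
  expect_equal(unname(f$x[2, ]), unname(encode_dacc(seqs[["b"]],
                                                    encoding_config(lag = 2))))

  seqs_bad <- c(seqs, d = "ACGNNNACGT")
  labels_bad <- c(labels, d = "cold")
  expect_error(encode_batch(seqs_bad, labels_bad, encoding_config(lag = 2)),
               "encoding failed.*d:")
  f2 <- encode_batch(seqs_bad, labels_bad, encoding_config(lag = 2),
                     skip_invalid = TRUE)
  expect_equal(nrow(f2$x), 3L)
  expect_equal(f2$skipped$id, "d")
  expect_match(f2$skipped$reason, "invalid character")

  expect_error(encode_batch(character(0)), "empty input")
  expect_error(encode_batch(seqs, c("hot", "cold", "warm")), "hot.*cold")
})
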