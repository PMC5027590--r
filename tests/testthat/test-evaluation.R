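test_that("metric closed forms are reproduced on hand-computed tables", {
  perfect <- classification_metrics(c(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(perfect, list(Se = 1, Sp = 1, Acc = 1, Mcc = 1))

  balanced <- classification_metrics(c(TP = 5, FP = 5, TN = 5, FN = 5))
  expect_equal(balanced$Acc, 0.5)
  expect_equal(balanced$Mcc, 0)

  # direct arithmetic oracle on an arbitrary table
  tp <- 37; fp <- 11; tn <- 48; fn <- 13
  m <- classification_metrics(c(TP = tp, FP = fp, TN = tn, FN = fn))
  expect_equal(m$Se, tp / (tp + fn))
  expect_equal(m$Sp, tn / (tn + fp))
  expect_equal(m$Acc, (tp + tn) / (tp + fp + tn + fn))
  expect_equal(m$Mcc, (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  expect_true(m$Mcc >= -1 && m$Mcc <= 1)

  # zero-denominator convention: Mcc defined as 0
  expect_equal(classification_metrics(c(TP = 5, FP = 5, TN = 0, FN = 0))$Mcc, 0)
  expect_error(classification_metrics(c(TP = -1, FP = 0, TN = 1, FN = 0)),
               "nonnegative")
})

test_that("evaluation results recompute exactly from their stored counts", {
  cl <- make_clusters(n_per = 8L, k = 3L, seed = 41L)
  res <- kfold_eval(cl$x, k = 4L, seed = 2L, labels = cl$y,
                    config = pipeline_config(reduce = FALSE))
  expect_s3_class(res, "recspot_eval")
  expect_equal(sum(res$counts), 16L)
  expect_equal(res$metrics, classification_metrics(res$counts))
  expect_equal(nrow(res$predictions), 16L)
})

test_that("jackknife holds out every sample once and nails separable data", {
  cl <- make_clusters(n_per = 12L, k = 3L, seed = 43L, shift = 6)
  cfg <- pipeline_config(reduce = FALSE)
  res <- jackknife_eval(cl$x, cfg, labels = cl$y)
  expect_equal(nrow(res$predictions), 24L)
  expect_equal(res$protocol, "jackknife")
  expect_equal(res$metrics$Acc, 1)

  # duplicated, perfectly separable points stay perfect under leave-one-out
  dup <- rbind(cl$x, cl$x)
  dup_y <- c(as.character(cl$y), as.character(cl$y))
  expect_equal(jackknife_eval(dup, cfg, labels = dup_y)$metrics$Acc, 1)

  expect_error(jackknife_eval(cl$x[c(1, 13, 14), ], cfg,
                              labels = cl$y[c(1, 13, 14)]),
               "2 samples per class")
})

test_that("k-fold at k = n reduces to the jackknife", {
  cl <- make_clusters(n_per = 6L, k = 3L, seed = 47L, shift = 6)
  cfg <- pipeline_config(reduce = FALSE)
  jk <- jackknife_eval(cl$x, cfg, labels = cl$y)
  kf <- kfold_eval(cl$x, k = 12L, seed = 3L, config = cfg, labels = cl$y)
  expect_equal(kf$counts, jk$counts)
  expect_equal(kf$predictions$decision, jk$predictions$decision)
})

test_that("k-fold evaluation is seed-deterministic and validates k", {
  cl <- make_clusters(n_per = 12L, k = 3L, seed = 53L)
  cfg <- pipeline_config(reduce = FALSE)
  r1 <- kfold_eval(cl$x, k = 4L, seed = 9L, config = cfg, labels = cl$y)
  r2 <- kfold_eval(cl$x, k = 4L, seed = 9L, config = cfg, labels = cl$y)
  expect_identical(r1$counts, r2$counts)
  expect_equal(r1$predictions$decision, r2$predictions$decision)

  expect_error(kfold_eval(cl$x, k = 13L, config = cfg, labels = cl$y),
               "smallest class")
  expect_error(kfold_eval(cl$x, k = 1L, config = cfg, labels = cl$y),
               "k must be >= 2")
})

test_that("per-fold PCA refits evaluate cleanly inside the protocols", {
  set.seed(59)
  sim <- simulate_recspots(synthetic_spec(n_pos = 15L, n_neg = 15L,
                                          length_range = c(60L, 90L),
                                          effect_size = 0.6, seed = 61L))
  feats <- encode_batch(sim$sequences, sim$labels, encoding_config(lag = 3))
  cfg <- pipeline_config(lag = 3, reduce = TRUE, w = 0.95)
  res <- kfold_eval(feats, k = 3L, seed = 1L, config = cfg)
  expect_equal(sum(res$counts), 30L)
  expect_gt(res$metrics$Acc, 0.5)

  # the leaky single-PCA shortcut exists but warns loudly
  expect_warning(jackknife_eval(feats, cfg, fast_pca = TRUE), "leaks")
})

test_that("lag sweeps are deterministic and locate a planted lag", {
  sim <- simulate_recspots(synthetic_spec(n_pos = 25L, n_neg = 25L,
                                          length_range = c(150L, 200L),
                                          signal_lag = 3L, effect_size = 0.5,
                                          seed = 67L))
  cfg <- pipeline_config(reduce = FALSE)
  tab <- lag_sweep(sim$sequences, sim$labels, lags = 1:4, config = cfg,
                   k = 5L, seed = 2L)
  expect_equal(tab$lag, 1:4)
  # the planted signal lives at lag 3: encodings that include it must win
  expect_gte(tab$lag[which.max(tab$Acc)], 3L)

  tab2 <- lag_sweep(sim$sequences, sim$labels, lags = 1:4, config = cfg,
                    k = 5L, seed = 2L)
  expect_identical(tab, tab2)

  single <- lag_sweep(sim$sequences, sim$labels, lags = 2L, config = cfg)
  expect_equal(nrow(single), 1L)
})
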