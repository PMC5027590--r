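test_that("well-separated clusters are fit perfectly and deterministically", {
  cl <- make_clusters()
  model <- train_classifier(cl$x, cl$y)
  p <- predict(model, cl$x)
  expect_equal(as.character(p$predicted), as.character(cl$y))
  expect_true(all(p$decision[cl$y == "hot"] > 0))
  expect_true(all(p$decision[cl$y == "cold"] < 0))

  # determinism: identical refits give identical decision values
  model2 <- train_classifier(cl$x, cl$y)
  p2 <- predict(model2, cl$x)
  expect_equal(p$decision, p2$decision, tolerance = 1e-10)

  # dual-coefficient invariants
  expect_equal(sum(model$alpha_full), 0, tolerance = 1e-6)
  expect_true(all(abs(model$coefs) <= model$C + 1e-8))

  # decision values do not depend on the batch row order
  idx <- rev(seq_len(nrow(cl$x)))
  expect_equal(predict(model, cl$x[idx, ])$decision, p$decision[idx])
})

test_that("training rejects degenerate inputs", {
  cl <- make_clusters(n_per = 10L)
  expect_error(train_classifier(cl$x[1:10, ], cl$y[1:10]), "both classes")
  bad <- cl$x; bad[1, 1] <- NA
  expect_error(train_classifier(bad, cl$y), "missing values")
  expect_error(predict(train_classifier(cl$x, cl$y), cl$x[, 1:2]),
               "dimension mismatch")
  expect_error(svm_config(C = -1), "positive")
  expect_error(svm_config(gamma = 0), "positive")
})

test_that("decision values agree with an independent LIBSVM fit", {
  skip_if_not_installed("e1071")
  cl <- make_clusters(n_per = 30L, k = 4L, seed = 9L)
  cfg <- svm_config(C = 8, gamma = 0.125)
  ours <- train_classifier(cl$x, cl$y, cfg)
  d_ours <- predict(ours, cl$x)$decision

  ref <- e1071::svm(cl$x, cl$y, kernel = "radial", cost = cfg$C,
                    gamma = cfg$gamma, scale = FALSE)
  d_ref <- as.vector(attr(predict(ref, cl$x, decision.values = TRUE),
                          "decision.values"))
  # align the reference sign to hot-positive before comparing
  if (mean(d_ref[cl$y == "hot"]) < 0) d_ref <- -d_ref
  expect_equal(ifelse(d_ours >= 0, "hot", "cold"),
               ifelse(d_ref >= 0, "hot", "cold"))
  expect_gt(cor(d_ours, d_ref), 0.999)
  expect_lt(max(abs(d_ours - d_ref)), 0.05)
})

test_that("swapping class labels negates decision values and weights", {
  cl <- make_clusters(n_per = 25L, k = 3L, seed = 13L)
  y_swapped <- factor(ifelse(cl$y == "hot", "cold", "hot"),
                      levels = c("hot", "cold"))
  m1 <- train_classifier(cl$x, cl$y)
  m2 <- train_classifier(cl$x, y_swapped)
  # agreement is bounded by the solver tolerance (1e-4), not exact
  expect_lt(max(abs(predict(m1, cl$x)$decision +
                      predict(m2, cl$x)$decision)), 1e-3)
  w1 <- discriminative_weights(m1, cl$x)
  w2 <- discriminative_weights(m2, cl$x)
  expect_lt(max(abs(w1$weight + w2$weight)), 1e-3)
})

test_that("discriminative weights follow the per-feature sum over sample weights", {
  cl <- make_clusters(n_per = 20L, k = 6L, seed = 17L)
  x <- cl$x
  x[, 4] <- 0             # identically-zero feature
  x[, 5] <- x[, 1]        # duplicated feature
  model <- train_classifier(x, cl$y)
  w <- discriminative_weights(model, x)

  # naive per-feature loop over W_j = sum_i A_i * M_ij
  naive <- vapply(seq_len(ncol(x)), function(j) {
    sum(model$alpha_full * x[, j])
  }, numeric(1L))
  expect_equal(w$weight, naive, tolerance = 1e-10)

  expect_equal(w$weight[4], 0)
  expect_equal(w$weight[5], w$weight[1], tolerance = 1e-12)
  expect_equal(w$rank, rank(-abs(w$weight), ties.method = "min"))
  expect_error(discriminative_weights(model, x[1:10, ]), "trained on")
})

test_that("grid search maximises CV accuracy with simplicity tie-breaks", {
  grid <- default_svm_grid()
  expect_true(any(grid$C == 8 & grid$gamma == 0.125))
  expect_true(all(range(log2(grid$C)) == c(-5, 15)))
  expect_true(all(range(log2(grid$gamma)) == c(-15, 3)))

  cl <- make_clusters(n_per = 20L, k = 3L, seed = 23L)
  one <- grid_search_svm(cl$x, cl$y, grid = data.frame(C = 2, gamma = 0.5),
                         folds = 3L, seed = 5L)
  expect_equal(one$C, 2)
  expect_equal(one$gamma, 0.5)

  small_grid <- data.frame(C = c(8, 2, 2), gamma = c(0.125, 0.125, 2))
  best <- grid_search_svm(cl$x, cl$y, grid = small_grid, folds = 3L, seed = 5L)
  tab <- attr(best, "table")
  # the selected pair attains the maximum CV accuracy, and no tied pair is
  # simpler (smaller C, then smaller gamma)
  expect_equal(max(tab$accuracy),
               tab$accuracy[tab$C == best$C & tab$gamma == best$gamma])
  ties <- tab[tab$accuracy == max(tab$accuracy), ]
  expect_equal(best$C, min(ties$C))
  expect_equal(best$gamma, min(ties$gamma[ties$C == best$C]))
  # the winner is at least as good as the default operating point
  def_acc <- tab$accuracy[tab$C == 8 & tab$gamma == 0.125]
  expect_gte(max(tab$accuracy), def_acc)
})
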