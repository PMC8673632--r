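make_clouds <- function(n_per = 500L, p = 4L, sep = 10, seed = 21L) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * p, 0, 1), n_per),
             matrix(stats::rnorm(n_per * p, sep, 1), n_per))
  y <- rep(0:1, each = n_per)
  test <- sample(nrow(X), floor(nrow(X) / 4))
  list(Xtr = X[-test, ], ytr = y[-test], Xte = X[test, ], yte = y[test])
}

test_that("both classifiers separate well-separated Gaussian clouds", {
  d <- make_clouds()
  for (spec in list(rf_spec(16), nn_spec(32, 32, 0.1, 0.05, 32))) {
    m <- train_classifier(spec, d$Xtr, d$ytr)
    expect_gte(mean(predict_labels(m, d$Xte) == d$yte), 0.99)
  }
})

test_that("training is deterministic given the seed", {
  d <- make_clouds(100L)
  for (spec in list(rf_spec(16, seed = 7), nn_spec(32, 32, 0.2, 0.05, 16,
                                                   seed = 7))) {
    m1 <- train_classifier(spec, d$Xtr, d$ytr)
    m2 <- train_classifier(spec, d$Xtr, d$ytr)
    expect_identical(predict_labels(m1, d$Xte), predict_labels(m2, d$Xte))
  }
})

test_that("single-class training yields a constant predictor", {
  X <- matrix(stats::rnorm(80), 20)
  m <- train_classifier(rf_spec(16), X, rep(3L, 20), n_classes = 5L)
  expect_true(all(predict_labels(m, X) == 3L))
  expect_error(train_classifier(rf_spec(16), X[0, , drop = FALSE],
                                integer(0)), "empty")
})

test_that("probabilities are normalised and consistent with labels", {
  d <- make_clouds(200L)
  m <- train_classifier(rf_spec(64), d$Xtr, d$ytr)
  p <- predict_proba(m, d$Xte)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
  expect_equal(max.col(p, ties.method = "first") - 1L,
               predict_labels(m, d$Xte))
  # unanimous forest votes give probability 1
  expect_gt(sum(p[, 1] == 1 | p[, 2] == 1), 0)
})

test_that("score ties break toward the lowest label id", {
  # hand-built single-leaf forest with an exactly 50/50 class distribution
  leaf <- matrix(c(-1, 0, -1, -1, 5, 5), 1, 6)
  m <- structure(list(kind = "rf", spec = rf_spec(16), fit = list(leaf),
                      n_classes = 2L, n_features = 2L, label_map = NULL,
                      feature_config = NULL, intensity_bounds = NULL,
                      meta = list(n_train = 10L, seed = 1L)),
                 class = "vx_model")
  p <- predict_proba(m, matrix(1, 3, 2))
  expect_equal(p[, 1], p[, 2])
  expect_equal(predict_labels(m, matrix(1, 3, 2)), rep(0L, 3))
})

test_that("predictions are batch-invariant", {
  d <- make_clouds(150L)
  m <- train_classifier(rf_spec(32), d$Xtr, d$ytr)
  whole <- predict_labels(m, d$Xte)
  parts <- c(predict_labels(m, d$Xte[1:50, ]),
             predict_labels(m, d$Xte[51:nrow(d$Xte), ]))
  expect_identical(whole, parts)
})

test_that("feature-width mismatch errors name the expected width", {
  d <- make_clouds(50L)
  m <- train_classifier(rf_spec(16), d$Xtr, d$ytr)
  expect_error(predict_labels(m, d$Xte[, 1:3]), "expected 4")
})

test_that("fitted forest depth never exceeds the cap", {
  set.seed(22)
  X <- matrix(stats::rnorm(4000), 1000)      # hard: pure noise forces depth
  y <- sample(0:1, 1000, TRUE)
  m <- train_classifier(rf_spec(16), X, y)
  expect_lte(rf_fitted_depth(m), 16L)
})

test_that("out-of-range hyperparameters are rejected", {
  expect_error(rf_spec(10), "16, 32, 64")
  expect_error(nn_spec(layer1 = 48), "32, 64, 128, 256")
  expect_error(nn_spec(dropout = 0.7), "dropout")
  expect_error(nn_spec(init_stddev = 2), "init_stddev")
  expect_error(nn_spec(minibatch = 3), "minibatch")
})

test_that("early stopping restores weights at least as good as the last", {
  d <- make_clouds(200L)
  m <- train_classifier(nn_spec(32, 32, 0.2, 0.05, 16), d$Xtr, d$ytr)
  expect_lte(m$fit$best_val_loss, m$fit$final_val_loss)
})

test_that("model bundles round-trip through save/load", {
  d <- make_clouds(100L)
  map <- label_map(c("bg", "fg"))
  fc <- feature_config()
  m <- train_classifier(rf_spec(16), d$Xtr, d$ytr, map = map,
                        feature_config = fc, intensity_bounds = c(0L, 65535L))
  dir <- withr::local_tempdir()
  save_model(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_model(dir)
  expect_identical(predict_proba(back, d$Xte), predict_proba(m, d$Xte))
  expect_equal(back$label_map$names, map$names)
  expect_equal(feature_length(back$feature_config), feature_length(fc))

  mn <- train_classifier(nn_spec(32, 32, 0.1, 0.05, 32), d$Xtr, d$ytr)
  dir2 <- withr::local_tempdir()
  save_model(mn, dir2)
  expect_identical(predict_labels(load_model(dir2), d$Xte),
                   predict_labels(mn, d$Xte))
})
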