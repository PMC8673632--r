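test_that("sample_config draws every variable uniformly", {
  space <- search_space("rf")
  set.seed(30)
  draws <- replicate(10000, sample_config(space), simplify = FALSE)
  for (d in draws[1:50]) expect_true(voxelseg:::validate_config(d, space))
  bins <- table(vapply(draws, `[[`, 0L, "h1_bins")) / 10000
  expect_true(all(abs(bins - 1 / 3) < 0.02))
  radii <- table(vapply(draws, `[[`, 0L, "h2_radius")) / 10000
  expect_true(all(abs(radii - 1 / 32) < 0.02))
})

test_that("sampling is reproducible under a fixed seed", {
  space <- search_space("nn")
  set.seed(31); a <- replicate(20, sample_config(space), simplify = FALSE)
  set.seed(31); b <- replicate(20, sample_config(space), simplify = FALSE)
  expect_identical(a, b)
})

test_that("mutate_config changes exactly one variable, uniformly chosen", {
  space <- search_space("rf")
  set.seed(32)
  base <- sample_config(space)
  V <- length(space$vars)
  which_changed <- character(10000)
  for (i in seq_len(10000)) {
    mut <- mutate_config(base, space)
    diff <- names(which(vapply(names(base), function(nm)
      !identical(base[[nm]], mut[[nm]]), TRUE)))
    expect_length(diff, 1L)
    expect_true(voxelseg:::validate_config(mut, space))
    which_changed[i] <- diff
  }
  freq <- table(which_changed) / 10000
  expect_length(freq, V)
  expect_true(all(abs(freq - 1 / V) < 0.02))
})

search_fixture <- function() {
  gen <- easy_two_texture()
  pyr <- build_pyramid(gen$volume, 2L)
  lab <- as.vector(gen$labels)
  coords <- all_coords(dim(gen$labels))
  set.seed(33)
  tr <- sort(sample(length(lab), 6000))
  va <- sort(sample(setdiff(seq_along(lab), tr), 4000))
  list(train = list(pyramid = pyr, coords = coords[tr, ], labels = lab[tr]),
       val = list(pyramid = pyr, coords = coords[va, ], labels = lab[va]))
}

test_that("the search recovers an easily separable problem and honours its
           contracts", {
  fx <- search_fixture()
  res <- two_stage_search(fx$train, fx$val, search_space("rf"),
                          search_budget(I_g = 10, I_l = 10, S_t = 150,
                                        S_v = 150, t = 5, seed = 4))
  expect_gte(res$best_accuracy, 0.98)
  expect_false(is.unsorted(res$trace$best_so_far))
  expect_equal(res$best_accuracy, max(res$trace$accuracy))
  keys <- apply(res$trace[, names(search_space("rf")$vars)], 1, paste,
                collapse = "|")
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(res$n_visited, nrow(res$trace))
})

test_that("the search is deterministic given its seed", {
  fx <- search_fixture()
  budget <- search_budget(I_g = 4, I_l = 4, S_t = 80, S_v = 80, t = 5,
                          seed = 9)
  r1 <- two_stage_search(fx$train, fx$val, search_space("rf"), budget)
  r2 <- two_stage_search(fx$train, fx$val, search_space("rf"), budget)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_config, r2$best_config)
})

test_that("a degenerate singleton space evaluates one config then times out", {
  fx <- search_fixture()
  space <- structure(list(classifier = "rf",
                          vars = list(h1_radius = 2L, h1_bins = 8L,
                                      h2_scale = 1L, h2_radius = 2L,
                                      h2_bins = 8L, lbp_scale = 0L,
                                      lbp_radius = 2L, n_trees = 16L)),
                     class = "vx_search_space")
  tick <- local({ t <- 0; function() { t <<- t + 1; t } })
  res <- two_stage_search(fx$train, fx$val, space,
                          search_budget(I_g = 100, I_l = 100, S_t = 50,
                                        S_v = 50, t = 5, seed = 2),
                          clock = tick)
  expect_equal(nrow(res$trace), 1L)
  expect_equal(res$n_visited, 1L)
})

test_that("empty labels in the training set are reported", {
  fx <- search_fixture()
  bad <- fx$train
  bad$labels[bad$labels == 1L] <- 0L
  expect_error(two_stage_search(bad, fx$val, search_space("rf"),
                                search_budget(I_g = 2, I_l = 2, S_t = 10,
                                              S_v = 10, seed = 1)),
               "label 1")
})

test_that("search traces serialise to CSV", {
  fx <- search_fixture()
  res <- two_stage_search(fx$train, fx$val, search_space("rf"),
                          search_budget(I_g = 2, I_l = 2, S_t = 50, S_v = 50,
                                        t = 5, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_search_trace(res, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(res$trace))
  expect_equal(back$accuracy, res$trace$accuracy)
})
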