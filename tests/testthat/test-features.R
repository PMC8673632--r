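test_that("histogram of a constant volume lands in a single bin", {
  pyr <- build_pyramid(volume(array(7L, c(9L, 9L, 9L))), 0L)
  h <- histogram_at(pyr, c(4L, 4L, 4L), histogram_spec(2, 0, 8))
  expect_equal(sum(h), 125L)
  expect_equal(sum(h > 0), 1L)
})

test_that("binning splits a two-valued neighbourhood as forced", {
  data <- array(0.1, c(3L, 3L, 3L))
  data[1:14] <- 0.9             # 13 voxels at 0.1, 14 at 0.9
  pyr <- build_pyramid(volume(data, intensity_min = 0, intensity_max = 1), 0L)
  h <- histogram_at(pyr, c(1L, 1L, 1L), histogram_spec(1, 0, 2))
  expect_equal(as.vector(h), c(13L, 14L))
})

test_that("histogram_at matches a plain-R recount, borders included", {
  vol <- rand_volume(c(20L, 20L, 20L), seed = 12)
  pyr <- build_pyramid(vol, 1L)
  rng <- c(vol$intensity_min, vol$intensity_max)
  set.seed(1)
  coords <- all_coords(c(20L, 20L, 20L))
  coords <- coords[sample(nrow(coords), 40L), ]
  for (r in 1:3) for (s in 0:1) {
    spec <- histogram_spec(r, s, 8)
    got <- histogram_at(pyr, coords, spec)
    level <- pyr$levels[[s + 1]]
    for (i in seq_len(nrow(coords))) {
      want <- r_hist_oracle(level, coords[i, ] %/% 2^s, r, rng[1], rng[2], 8)
      expect_equal(as.vector(got[, i]), want)
    }
  }
})

test_that("incremental slab histograms equal the per-voxel path", {
  vol <- rand_volume(c(16L, 16L, 16L), seed = 13)
  pyr <- build_pyramid(vol, 0L)
  spec <- histogram_spec(2, 0, 8)
  slabs <- iter_slabs(vol, 5L, halo = 2L)
  got <- do.call(cbind, lapply(slabs, function(s)
    slab_histograms(pyr, s, spec)))
  for (s in slabs) {
    zr <- s$z_range
    g <- expand.grid(z = zr[1]:(zr[2] - 1L), y = 0:15, x = 0:15)
    coords <- as.matrix(g[order(g$x, g$y, g$z), ])
    dimnames(coords) <- NULL
    expect_identical(slab_histograms(pyr, s, spec),
                     histogram_at(pyr, coords, spec))
  }
  expect_equal(unique(colSums(got)), 125L)  # conservation at every step
})

test_that("slab histograms conserve counts and need a sufficient halo", {
  vol <- rand_volume(c(12L, 12L, 12L), seed = 14)
  pyr <- build_pyramid(vol, 1L)
  slabs <- iter_slabs(vol, 4L, halo = 1L)
  expect_error(slab_histograms(pyr, slabs[[1]], histogram_spec(3, 1, 8)),
               "halo >= 6")
  u <- volume(array(5L, c(12L, 12L, 12L)))
  pu <- build_pyramid(u, 0L)
  h <- slab_histograms(pu, iter_slabs(u, 12L, halo = 2L)[[1]],
                       histogram_spec(2, 0, 4))
  expect_equal(nrow(unique(t(h))), 1L)      # uniform volume: all identical
})

test_that("lbp_code implements the uniform rotation-invariant coding", {
  expect_equal(lbp_code(matrix(3, 3, 3)), 8L)        # ties count as >=
  patch <- matrix(1, 3, 3); patch[2, 2] <- 5
  expect_equal(lbp_code(patch), 0L)
  expect_equal(lbp_code(patch_from_bits(rep(c(1, 0), 4))), 9L)
  expect_equal(lbp_code(patch_from_bits(c(1, 1, 1, 0, 0, 0, 0, 0))), 3L)
  codes <- vapply(0:255, function(p)
    lbp_code(patch_from_bits(as.integer(intToBits(p))[1:8])), 0L)
  expect_setequal(unique(codes), 0:9)
})

test_that("lbp_codes (volume path) agrees with lbp_code patch by patch", {
  vol <- rand_volume(c(7L, 7L, 7L), seed = 15, max_val = 5L)  # many ties
  level <- array(as.double(vol$data), dim(vol$data))
  for (plane in c("xy", "yz", "xz")) {
    codes <- lbp_codes(level, plane)
    for (i in 1:20) {
      p <- all_coords(c(7L, 7L, 7L))[sample(343, 1), ]
      want <- r_lbp_plane_oracle(level, p, plane, 0L)
      expect_equal(codes[p[1] + 1L, p[2] + 1L, p[3] + 1L],
                   which(want == 1L) - 1L)
    }
  }
})

test_that("lbp plane histograms count codes over the in-plane window", {
  const <- array(1, c(9L, 9L, 9L))
  h <- lbp_plane_histogram(const, c(4L, 4L, 4L), "xy", r = 2L)
  expect_equal(as.vector(h), c(rep(0L, 8), 25L, 0L))  # all code 8
  h1 <- lbp_plane_histogram(const, c(0L, 0L, 0L), "yz", r = 1L)
  expect_equal(sum(h1), 9L)

  vol <- rand_volume(c(10L, 10L, 10L), seed = 16)
  level <- array(as.double(vol$data), dim(vol$data))
  set.seed(2)
  for (plane in c("xy", "yz", "xz")) {
    for (i in 1:5) {
      p <- all_coords(c(10L, 10L, 10L))[sample(1000, 1), ]
      got <- lbp_plane_histogram(level, p, plane, r = 3L)
      expect_equal(as.vector(got), r_lbp_plane_oracle(level, p, plane, 3L))
    }
  }
})

test_that("lbp_code is invariant under cyclic rotations of the ring", {
  for (p in 0:255) {
    bits <- as.integer(intToBits(p))[1:8]
    base <- lbp_code(patch_from_bits(bits))
    for (k in 1:7) {
      rot <- bits[c((k + 1):8, 1:k)]
      expect_identical(lbp_code(patch_from_bits(rot)), base)
    }
  }
})

test_that("the three-plane LBP feature is a 30-vector with plane structure", {
  vol <- rand_volume(c(12L, 12L, 12L), seed = 17)
  pyr <- build_pyramid(vol, 1L)
  f <- lbp_top_feature(pyr, c(6L, 6L, 6L), lbp_spec(1, 2))
  expect_equal(nrow(f), 30L)
  expect_equal(as.vector(colSums(matrix(f, 10))), rep(25L, 3))

  cpyr <- build_pyramid(volume(array(4L, c(8L, 8L, 8L))), 0L)
  fc <- lbp_top_feature(cpyr, c(4L, 4L, 4L), lbp_spec(0, 2))
  expect_equal(which(fc > 0), c(9L, 19L, 29L))       # code 8 in each block

  # volume varying only along z: xy plane is constant (all code 8),
  # yz and xz planes see the gradient
  g <- volume(array(rep(seq(0, 1, length.out = 12), 144), c(12L, 12L, 12L)))
  gp <- build_pyramid(g, 0L)
  fg <- lbp_top_feature(gp, c(6L, 6L, 6L), lbp_spec(0, 2))
  expect_equal(as.vector(fg[1:10]), c(rep(0L, 8), 25L, 0L))
  expect_false(all(fg[11:20] == fg[1:10]))
  expect_false(all(fg[21:30] == fg[1:10]))
})

test_that("compose_features lays out [intensity | hist1 | hist2 | lbp]", {
  vol <- rand_volume(c(16L, 16L, 16L), seed = 18)
  pyr <- build_pyramid(vol, 1L)
  config <- feature_config(histogram_spec(3, 0, 32),
                           histogram_spec(12, 0, 16), lbp_spec(0, 15))
  expect_equal(feature_length(config), 79L)   # 1 + 32 + 16 + 30
  coords <- rbind(c(3L, 4L, 5L), c(8L, 8L, 8L), c(3L, 4L, 5L))
  X <- compose_features(pyr, coords, config)
  expect_equal(dim(X), c(3L, 79L))
  expect_equal(X[1, ], X[3, ])                # identical coords, identical rows
  expect_false(anyNA(X))
  # intensity feature equals the stored voxel value (normalised)
  raw <- compose_features(pyr, coords, config, normalise = FALSE)
  expect_equal(unname(raw[2, 1]), vol$data[9, 9, 9])
  # normalised histogram blocks sum to 1
  expect_equal(unname(rowSums(X[, 2:33])), rep(1, 3))
  expect_equal(unname(rowSums(X[, 34:49])), rep(1, 3))
  expect_equal(unname(rowSums(X[, 50:79])), rep(3, 3))  # three planes
})

test_that("block (slab) feature composition equals per-coordinate features", {
  vol <- rand_volume(c(20L, 10L, 10L), seed = 19)
  pyr <- build_pyramid(vol, 1L)
  config <- feature_config(histogram_spec(2, 0, 8), histogram_spec(3, 1, 8),
                           lbp_spec(1, 2))
  for (zr in list(c(0L, 7L), c(7L, 20L))) {
    g <- expand.grid(z = zr[1]:(zr[2] - 1L), y = 0:9, x = 0:9)
    coords <- as.matrix(g[order(g$x, g$y, g$z), ])
    dimnames(coords) <- NULL
    want <- compose_features(pyr, coords, config)
    got <- voxelseg:::compose_features_block(pyr, zr, config)
    expect_equal(unname(got), unname(want), ignore_attr = TRUE)
  }
})

test_that("features are translation-consistent away from borders", {
  set.seed(20)
  base <- array(sample.int(1000, 12^3, TRUE), c(12L, 12L, 12L))
  shifted <- array(0L, c(12L, 12L, 12L))
  shifted[1:10, 1:10, 1:10] <- base[3:12, 3:12, 3:12]
  shifted[11:12, , ] <- base[1:2, , ]; shifted[, 11:12, ] <- base[, 1:2, ]
  shifted[, , 11:12] <- base[, , 1:2]
  p1 <- build_pyramid(volume(base, intensity_min = 1L,
                             intensity_max = 1000L), 0L)
  p2 <- build_pyramid(volume(shifted, intensity_min = 1L,
                             intensity_max = 1000L), 0L)
  config <- feature_config(histogram_spec(2, 0, 8), histogram_spec(3, 0, 8),
                           lbp_spec(0, 2))
  f1 <- compose_features(p1, c(7L, 7L, 7L), config)
  f2 <- compose_features(p2, c(5L, 5L, 5L), config)
  expect_equal(unname(f1), unname(f2), ignore_attr = TRUE)
})
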