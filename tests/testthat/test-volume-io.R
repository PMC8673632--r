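test_that("TIFF slice-stack round-trip is bit-exact and stacks in z order", {
  vol <- rand_volume(c(10L, 32L, 32L), seed = 2, max_val = 60000L)
  dir <- withr::local_tempdir()
  write_volume(vol, dir, format = "tiff_stack")
  expect_length(list.files(dir, pattern = "\\.tif$"), 10L)
  back <- read_volume(dir)
  expect_identical(dim(back$data), c(10L, 32L, 32L))
  expect_identical(back$data, vol$data)
})

test_that("multi-page TIFF and 8-bit TIFF round-trip bit-exactly", {
  vol <- rand_volume(c(5L, 9L, 13L), seed = 3, max_val = 65536L)
  vol$data <- vol$data - 1L     # include 0 and possibly 65535
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(volume(vol$data), f, format = "tiff")
  expect_identical(read_volume(f)$data, vol$data)

  v8 <- rand_volume(c(3L, 7L, 7L), seed = 4, max_val = 256L)
  v8$data <- v8$data - 1L
  f8 <- withr::local_tempfile(fileext = ".tif")
  write_volume(volume(v8$data), f8, format = "tiff", bits = 8L)
  expect_identical(read_volume(f8)$data, v8$data)
})

test_that("our TIFF codec agrees with Python tifffile both ways", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  vol <- rand_volume(c(4L, 11L, 17L), seed = 9, max_val = 65000L)
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(vol, f, format = "tiff")
  csv <- withr::local_tempfile(fileext = ".txt")
  status <- system2("python", c("-c", shQuote(paste0(
    "import tifffile, numpy as np; a = tifffile.imread('", f, "'); ",
    "np.savetxt('", csv, "', a.reshape(-1), fmt='%d')"))))
  expect_equal(status, 0L)
  vals <- scan(csv, what = integer(), quiet = TRUE)
  expect_identical(array(vals, dim = rev(dim(vol$data))),
                   aperm(vol$data, 3:1))   # tifffile reads (z, y, x) row-major

  f2 <- withr::local_tempfile(fileext = ".tif")
  status <- system2("python", c("-c", shQuote(paste0(
    "import tifffile, numpy as np; rng = np.random.default_rng(0); ",
    "a = rng.integers(0, 65535, size=(6, 8, 5), dtype=np.uint16); ",
    "tifffile.imwrite('", f2, "', a, photometric='minisblack'); ",
    "np.savetxt('", csv, "', a.reshape(-1), fmt='%d')"))))
  expect_equal(status, 0L)
  vals <- scan(csv, what = integer(), quiet = TRUE)
  back <- read_volume(f2)
  expect_identical(aperm(back$data, 3:1), array(vals, dim = rev(dim(back$data))))
})

test_that("HDF5 round-trip is bit-exact", {
  vol <- rand_volume(c(6L, 10L, 8L), seed = 5, max_val = 65536L)
  f <- withr::local_tempfile(fileext = ".h5")
  write_volume(vol, f, format = "hdf5")
  expect_identical(read_volume(f)$data, vol$data)
})

test_that("volume records global bounds; constant volume has min = max", {
  v <- volume(array(7L, c(2L, 3L, 4L)))
  expect_equal(v$intensity_min, 7L)
  expect_equal(v$intensity_max, 7L)
  expect_error(volume(array(1, c(2, 2))), "3D")
})

test_that("inconsistent slice shapes are a format error", {
  dir <- withr::local_tempdir()
  tiff_write <- voxelseg:::tiff_write
  tiff_write(list(matrix(1L, 4, 4)), file.path(dir, "a.tif"))
  tiff_write(list(matrix(1L, 5, 4)), file.path(dir, "b.tif"))
  expect_error(read_volume(dir), "inconsistent slice shapes")
})

test_that("label maps validate their invariants", {
  m <- label_map(c("unlabelled", "bone", "soft"))
  expect_equal(m$ids, 0:2)
  expect_equal(m$unlabelled_id, 0L)
  expect_equal(m$ignore_id, 255L)
  expect_false(m$ignore_id %in% m$ids)
  expect_error(label_map("one"), "at least 2")
  expect_error(label_map(c("a", "a")), "unique")
})

test_that("annotations round-trip via PNG with filename-encoded z", {
  map <- label_map(c("bg", "fg"))
  lab <- matrix(255L, 8, 6)
  lab[2:3, 2] <- 1L
  lab[5, ] <- 0L
  s <- annotated_slice(42L, lab, map)
  dir <- withr::local_tempdir()
  write_annotations(list(s), dir)
  expect_true(file.exists(file.path(dir, "labels_z00042.png")))
  back <- read_annotations(list.files(dir, full.names = TRUE), map,
                           shape = c(64L, 8L, 6L))
  expect_equal(back[[1]]$slice_index, 42L)
  expect_identical(back[[1]]$labels, lab)
  # per-label voxel counts follow directly
  expect_equal(sum(back[[1]]$labels == 1L), 2L)
})

test_that("unknown label codes and shape mismatches are rejected", {
  map <- label_map(c("bg", "fg"))
  expect_error(annotated_slice(0L, matrix(2L, 4, 4), map), "not in label map")
  lab <- matrix(0L, 4, 4)
  dir <- withr::local_tempdir()
  write_annotations(list(annotated_slice(1L, lab)), dir)
  expect_error(read_annotations(list.files(dir, full.names = TRUE), map,
                                shape = c(4L, 5L, 5L)), "does not match")
  expect_error(read_annotations(list.files(dir, full.names = TRUE), map,
                                shape = c(1L, 4L, 4L)), "outside volume")
})

test_that("an all-ignore slice contributes zero training voxels", {
  s <- annotated_slice(0L, matrix(255L, 4, 4))
  expect_error(sample_voxels(list(s), 10), "no labelled voxels")
})

test_that("slab z-ranges partition [0, nz) for every thickness", {
  for (nz in c(1:20, 37L, 100L)) {
    vol <- volume(array(0L, c(nz, 2L, 2L)))
    for (thick in seq_len(nz)) {
      slabs <- iter_slabs(vol, thick)
      ranges <- do.call(rbind, lapply(slabs, `[[`, "z_range"))
      expect_equal(ranges[1, 1], 0L)
      expect_equal(ranges[nrow(ranges), 2], nz)
      if (nrow(ranges) > 1)
        expect_equal(ranges[-1, 1], ranges[-nrow(ranges), 2])
    }
  }
})

test_that("slabs carry clamped halos; oversized halo warns, not errors", {
  vol <- rand_volume(c(10L, 4L, 4L))
  slabs <- iter_slabs(vol, 4L, halo = 2L)
  expect_equal(slabs[[1]]$loaded_range, c(0L, 6L))
  expect_equal(slabs[[2]]$loaded_range, c(2L, 10L))
  expect_equal(dim(slabs[[2]]$data)[1], 8L)
  expect_warning(s1 <- iter_slabs(volume(array(0L, c(5L, 2L, 2L))), 100L,
                                  halo = 50L), "clamped")
  expect_length(s1, 1L)
  expect_equal(s1[[1]]$z_range, c(0L, 5L))
  expect_equal(s1[[1]]$loaded_range, c(0L, 5L))
})

test_that("a per-voxel map applied slab-wise equals the whole-volume map", {
  vol <- rand_volume(c(20L, 20L, 20L), seed = 8)
  whole <- vol$data^2 %% 97L
  for (thick in c(1L, 7L, 20L)) {
    parts <- lapply(iter_slabs(vol, thick), function(s) {
      zr <- s$z_range
      s$data[(zr[1] - s$loaded_range[1] + 1L):(zr[2] - s$loaded_range[1]), , ,
             drop = FALSE]^2 %% 97L
    })
    got <- do.call(abind_z, parts)
    expect_identical(got, whole)
  }
})
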