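# Synthetic labelled phantoms: volumes whose regions differ in intensity
# distribution and/or spatial texture, so every pipeline stage is testable
# without external scan data.  Intensities are generated in the unit
# interval and quantised to 16 bits, exercising the integer I/O path.

#' Describe one textured region of a phantom
#'
#' @param name label name.
#' @param geometry one of
#'   `list(type = "sphere", center, radius)` (center in `(z, y, x)`, 0-based),
#'   `list(type = "shell", center, r_inner, r_outer)` (inner radius
#'   exclusive, outer inclusive),
#'   `list(type = "halfspace", axis, from, to)` (`axis` in `"z","y","x"`,
#'   half-open coordinate interval), or `list(type = "rest")` (whatever no
#'   earlier region claimed).
#' @param intensity one of
#'   `list(type = "gaussian", mean, sd)`,
#'   `list(type = "smooth_noise", mean, sd, corr_len)` (Gaussian noise
#'   low-pass filtered to correlation length `corr_len` voxels, rescaled to
#'   `sd`), or
#'   `list(type = "stripes", mean, contrast, sd, period, axis)` (square
#'   wave of the given period along `axis`, amplitude `contrast`, plus
#'   Gaussian noise of `sd`).
#' @export
texture_region <- function(name, geometry, intensity) {
  structure(list(name = name, geometry = geometry, intensity = intensity),
            class = "vx_texture_region")
}

axis_index <- function(axis) match(axis, c("z", "y", "x"))

region_mask <- function(geometry, shape) {
  zc <- slice.index(array(0, shape), 1) - 1L
  yc <- slice.index(array(0, shape), 2) - 1L
  xc <- slice.index(array(0, shape), 3) - 1L
  switch(geometry$type,
    sphere = {
      d2 <- (zc - geometry$center[1])^2 + (yc - geometry$center[2])^2 +
        (xc - geometry$center[3])^2
      d2 <= geometry$radius^2
    },
    shell = {
      d2 <- (zc - geometry$center[1])^2 + (yc - geometry$center[2])^2 +
        (xc - geometry$center[3])^2
      d2 > geometry$r_inner^2 & d2 <= geometry$r_outer^2
    },
    halfspace = {
      cc <- list(zc, yc, xc)[[axis_index(geometry$axis)]]
      cc >= geometry$from & cc < geometry$to
    },
    rest = array(TRUE, shape),
    stop("unknown geometry type: ", geometry$type))
}

region_intensity <- function(model, shape) {
  n <- prod(shape)
  switch(model$type,
    gaussian = array(stats::rnorm(n, model$mean, model$sd), shape),
    smooth_noise = {
      raw <- array(stats::rnorm(n), shape)
      sm <- blur3d(raw, model$corr_len)
      sm <- sm / stats::sd(sm)
      array(model$mean + model$sd * sm, shape)
    },
    stripes = {
      coord <- slice.index(array(0, shape), axis_index(model$axis)) - 1L
      wave <- ifelse((coord %/% (model$period / 2)) %% 2 == 0, 1, -1)
      model$mean + model$contrast * wave +
        array(stats::rnorm(n, 0, model$sd), shape)
    },
    stop("unknown intensity model: ", model$type))
}

#' Generate a labelled multi-texture phantom volume
#'
#' Region geometries are applied in order and must partition the volume
#' exactly (a trailing `"rest"` region claims the remainder); overlapping
#' geometries are an error.  Intensities are drawn per region, clamped to
#' the unit interval and quantised to 16-bit integers.  The generator is a
#' pure function of `(specs, shape, seed)`.
#'
#' @param specs list of [texture_region()], length >= 2.
#' @param shape volume shape `(nz, ny, nx)`, each >= 16.
#' @param seed RNG seed.
#' @return list with `volume` (a [volume()], 16-bit integer data), `labels`
#'   (integer array of 0-based region ids) and `map` (a [label_map()]).
#' @export
make_textured_volume <- function(specs, shape, seed = 1L) {
  if (length(specs) < 2L) stop("need at least 2 regions")
  if (any(shape < 16L)) stop("shape must be at least 16 in every dimension")
  set.seed(seed)
  labels <- array(NA_integer_, shape)
  for (i in seq_along(specs)) {
    mask <- region_mask(specs[[i]]$geometry, shape)
    if (specs[[i]]$geometry$type == "rest") mask <- mask & is.na(labels)
    if (any(!is.na(labels[mask])))
      stop("overlapping geometries: region '", specs[[i]]$name,
           "' intersects an earlier region")
    labels[mask] <- i - 1L
  }
  if (anyNA(labels))
    stop("geometries do not cover the volume; add a 'rest' region")
  data <- array(0, shape)
  for (i in seq_along(specs)) {
    vals <- region_intensity(specs[[i]]$intensity, shape)
    sel <- labels == i - 1L
    data[sel] <- vals[sel]
  }
  q <- array(as.integer(round(pmin(pmax(data, 0), 1) * 65535)), shape)
  list(volume = volume(q),
       labels = labels,
       map = label_map(vapply(specs, function(s) s$name, "")))
}

#' The default three-region phantom
#'
#' A toy stand-in for a wrapped specimen: a striped "wrapping" background, a
#' smoothed-noise "soft tissue" shell and a bright "bone" core, with region
#' mean intensities separated by several noise standard deviations and
#' distinct spatial textures.
#'
#' @param shape volume shape (default 64^3).
#' @param seed RNG seed.
#' @return as [make_textured_volume()].
#' @export
default_phantom <- function(shape = c(64L, 64L, 64L), seed = 1L) {
  ctr <- (shape - 1) / 2
  make_textured_volume(list(
    texture_region("bone",
                   list(type = "sphere", center = ctr, radius = 0.2 * min(shape)),
                   list(type = "gaussian", mean = 0.80, sd = 0.02)),
    texture_region("soft_tissue",
                   list(type = "shell", center = ctr,
                        r_inner = 0.2 * min(shape), r_outer = 0.4 * min(shape)),
                   list(type = "smooth_noise", mean = 0.55, sd = 0.02,
                        corr_len = 2)),
    texture_region("wrapping",
                   list(type = "rest"),
                   list(type = "stripes", mean = 0.30, contrast = 0.06,
                        sd = 0.02, period = 6, axis = "y"))),
    shape, seed)
}

#' A pair of textures separable by LBP but not by histograms
#'
#' Two half-spaces (split along z) carry the same stripes-plus-noise
#' texture, differing only in stripe orientation: stripes along y in the
#' lower half, along x in the upper half.  The upper half is constructed as
#' an exact mirrored transpose of the lower one under the involution
#' `(z, y, x) -> (nz-1-z, x, y)`.  That map swaps the two labels, maps
#' volume faces to volume faces, and maps every cubic neighbourhood to a
#' transposed cubic neighbourhood with an identical value multiset -- so
#' every voxel has a twin of the opposite class whose intensity, whose
#' neighbourhood histograms at every radius and scale, and whose in-plane
#' (xy) LBP histogram are *exactly* equal.  Intensity and histogram features
#' therefore carry provably zero class signal (including at faces and at
#' the region boundary), while the transpose exchanges the yz and xz LBP
#' planes, which remain fully discriminative.  Stripe phases are drawn at
#' random per stripe column so the texture is not a single global grating.
#'
#' @param shape volume shape `(nz, ny, nx)`: `nz` even, `ny == nx`, each
#'   >= 32.
#' @param seed RNG seed.
#' @return as [make_textured_volume()]: `volume`, `labels`, `map` (labels
#'   `stripes_y` = 0 for `z < nz/2`, `stripes_x` = 1 above).
#' @export
make_lbp_discriminable_pair <- function(shape = c(64L, 64L, 64L), seed = 1L) {
  if (any(shape < 32L)) stop("shape must be at least 32 in every dimension")
  if (shape[2] != shape[3]) stop("ny and nx must be equal (transpose symmetry)")
  if (shape[1] %% 2L != 0L) stop("nz must be even")
  set.seed(seed)
  mean_v <- 0.5; contrast <- 0.12; sd_n <- 0.03; period <- 4L
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  half <- nz %/% 2L
  sq <- function(t) ifelse((t %/% (period %/% 2L)) %% 2L == 0L, 1, -1)
  # lower half: stripes along y, phase random per x column
  phi <- sample.int(period, nx, replace = TRUE) - 1L
  wave_yx <- outer(0:(ny - 1L), phi, function(y, p) sq(y + p))  # (ny, nx)
  data <- array(0, shape)
  for (z in seq_len(nz)) {
    noise <- matrix(stats::rnorm(ny * nx, 0, sd_n), ny, nx)
    if (z <= half) {
      data[z, , ] <- mean_v + contrast * wave_yx + noise
    } else {
      # mirrored transpose of the already-generated lower half
      data[z, , ] <- t(data[nz + 1L - z, , ])
    }
  }
  labels <- array(0L, shape)
  labels[(half + 1L):nz, , ] <- 1L
  q <- array(as.integer(round(pmin(pmax(data, 0), 1) * 65535)), shape)
  list(volume = volume(q), labels = labels,
       map = label_map(c("stripes_y", "stripes_x")))
}

#' Extract annotated slices from a dense label array
#'
#' Convenience for driving the pipeline from generated phantoms: turns the
#' given z-slices of a full label array into [annotated_slice()] objects.
#'
#' @param labels integer 3D array of label ids.
#' @param slice_indices 0-based z indices to annotate.
#' @export
annotations_from_labels <- function(labels, slice_indices) {
  lapply(as.integer(slice_indices), function(z)
    annotated_slice(z, labels[z + 1L, , ]))
}
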