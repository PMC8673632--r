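#' Neighbourhood histogram specification
#'
#' A k-bin histogram of intensities in the cube of side `2r+1` centred on
#' the voxel, taken at pyramid scale `s`.  Bins are linearly spaced over the
#' recorded scale-0 intensity range of the volume; values pushed outside
#' that range (possible only after blurring) are clamped into the end bins.
#'
#' @param radius neighbourhood radius `r` in voxels at the chosen scale, >= 1.
#' @param scale pyramid level `s`, >= 0.
#' @param bins number of bins `k`, >= 2.
#' @export
histogram_spec <- function(radius, scale = 0L, bins = 16L) {
  stopifnot(radius >= 1L, scale >= 0L, bins >= 2L)
  structure(list(radius = as.integer(radius), scale = as.integer(scale),
                 bins = as.integer(bins)),
            class = "vx_histogram_spec")
}

#' Three-orthogonal-plane LBP specification
#'
#' Uniform rotation-invariant LBP codes (10 possible codes) are computed for
#' every voxel of the scale-`s` level on each of the xy, yz and xz planes
#' from the 8 in-plane neighbours at radius 1; the feature is the
#' concatenation of the three 10-bin code histograms over the in-plane
#' `(2r+1)^2` neighbourhood, length 30.
#'
#' @param scale pyramid level, >= 0.
#' @param radius 2D histogram neighbourhood radius, >= 1.
#' @export
lbp_spec <- function(scale = 0L, radius = 4L) {
  stopifnot(radius >= 1L, scale >= 0L)
  structure(list(scale = as.integer(scale), radius = as.integer(radius),
                 code_count = 10L),
            class = "vx_lbp_spec")
}

#' Full per-voxel feature recipe
#'
#' The feature vector is the concatenation of: the voxel intensity at scale
#' 0; a short-range intensity histogram at scale 0 (`hist1`); a long-range
#' intensity histogram (`hist2`, any scale); and the three-orthogonal-plane
#' LBP histogram (30 values).  Total length `1 + k1 + k2 + 30`.
#'
#' @param hist1 short-range [histogram_spec()]; its scale must be 0.
#' @param hist2 long-range [histogram_spec()].
#' @param lbp an [lbp_spec()].
#' @param include_intensity include the raw voxel intensity feature.
#' @export
feature_config <- function(hist1 = histogram_spec(3, 0, 16),
                           hist2 = histogram_spec(8, 1, 16),
                           lbp = lbp_spec(0, 4),
                           include_intensity = TRUE) {
  if (hist1$scale != 0L)
    stop("hist1 is the short-range histogram: its scale is fixed to 0")
  structure(list(hist1 = hist1, hist2 = hist2, lbp = lbp,
                 include_intensity = include_intensity),
            class = "vx_feature_config")
}

#' Total feature vector length of a configuration
#' @param config a [feature_config()].
#' @export
feature_length <- function(config) {
  as.integer(config$include_intensity) + config$hist1$bins +
    config$hist2$bins + 3L * config$lbp$code_count
}

#' @export
print.vx_feature_config <- function(x, ...) {
  cat(sprintf(paste0("<vx_feature_config> len %d: intensity | hist1(r=%d,",
                     "k=%d,s=0) | hist2(r=%d,k=%d,s=%d) | lbp(r=%d,s=%d)\n"),
              feature_length(x), x$hist1$radius, x$hist1$bins,
              x$hist2$radius, x$hist2$bins, x$hist2$scale,
              x$lbp$radius, x$lbp$scale))
  invisible(x)
}

#' Linearly spaced histogram bin edges over the recorded intensity range
#' @param k number of bins.
#' @param lo,hi recorded scale-0 intensity bounds.
#' @return numeric vector of `k + 1` strictly increasing edges.
#' @export
bin_edges <- function(k, lo, hi) {
  if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5 }  # constant volume
  seq(lo, hi, length.out = k + 1L)
}

intensity_range <- function(pyr) {
  lo <- pyr$intensity_min; hi <- pyr$intensity_max
  if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
  c(lo, hi)
}

clamp_to_level <- function(mapped, ldim) {
  for (j in 1:3) mapped[, j] <- pmin(mapped[, j], ldim[j] - 1L)
  mapped
}

as_coord_matrix <- function(coords) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  storage.mode(coords) <- "integer"
  coords
}

#' Neighbourhood histogram at given scale-0 coordinates
#'
#' Direct (per-coordinate) computation; the reference path against which the
#' incremental [slab_histograms()] is verified.  Borders use edge-replicated
#' padding, so counts always sum to `(2r+1)^3`.
#'
#' @param pyr a [build_pyramid()] result.
#' @param coords `(z, y, x)` 0-based scale-0 coordinate(s); vector or n x 3
#'   matrix.
#' @param spec a [histogram_spec()].
#' @return `k x n` integer matrix of counts.
#' @export
histogram_at <- function(pyr, coords, spec) {
  coords <- as_coord_matrix(coords)
  level <- pyramid_level(pyr, spec$scale)
  d <- dim(level)
  mapped <- clamp_to_level(map_coordinate(coords, spec$scale), d)
  rng <- intensity_range(pyr)
  key <- mapped[, 1] + d[1] * (mapped[, 2] + d[2] * mapped[, 3])
  u <- !duplicated(key)
  h <- cpp_hist_at(level, d, mapped[u, , drop = FALSE], spec$radius,
                   rng[1], rng[2], spec$bins)
  h[, match(key, key[u]), drop = FALSE]
}

slab_level_range <- function(z_range, s, level_nz) {
  step <- 2^s
  c(min(z_range[1] %/% step, level_nz - 1L),
    min((z_range[2] - 1L) %/% step + 1L, level_nz))
}

# column indices into a level block (dim (lz1-lz0, nyl, nxl), z fastest) for
# every scale-0 voxel of the slab z_range, in order z, then y, then x.
# Mapped coordinates are clamped at the level edges (relevant only when a
# dimension is not divisible by 2^s, where floor level shapes drop the last
# partial cell).
slab_block_index <- function(z_range, shape0, s, lz0, ldim) {
  step <- 2^s
  zi <- pmin((z_range[1]:(z_range[2] - 1L)) %/% step, lz0 + ldim[1] - 1L) - lz0
  yi <- pmin((0:(shape0[2] - 1L)) %/% step, ldim[2] - 1L)
  xi <- pmin((0:(shape0[3] - 1L)) %/% step, ldim[3] - 1L)
  nzs <- length(zi)
  rep(zi, times = shape0[2] * shape0[3]) +
    ldim[1] * (rep(rep(yi, each = nzs), times = shape0[3]) +
               ldim[2] * rep(xi, each = nzs * shape0[2])) + 1L
}

#' Incremental per-voxel histograms for a whole slab
#'
#' Computes the neighbourhood histogram of every voxel whose z lies in the
#' slab's range, using the incremental sliding-window algorithm: along each
#' `(y, x)` column the first cube histogram is counted in full, then each
#' step subtracts the departing plane at `z - r` (of the previous centre)
#' and adds the arriving plane at `z + r`, an O(r^2) update per voxel.
#' Results are voxel-for-voxel identical to [histogram_at()].
#'
#' @param pyr a [build_pyramid()] result.
#' @param slab one element of [iter_slabs()] (or a list with a `z_range`
#'   field and a `halo` field).
#' @param spec a [histogram_spec()].
#' @return `k x n` integer count matrix, columns ordered z (fastest), y, x
#'   over the slab.
#' @export
slab_histograms <- function(pyr, slab, spec) {
  need <- spec$radius * 2^spec$scale
  if (!is.null(slab$halo) && slab$halo < need)
    stop("slab halo ", slab$halo, " insufficient: spec requires halo >= ",
         need, " slices at scale 0")
  level <- pyramid_level(pyr, spec$scale)
  d <- dim(level)
  lr <- slab_level_range(slab$z_range, spec$scale, d[1])
  rng <- intensity_range(pyr)
  block <- cpp_hist_block(level, d, lr[1], lr[2], spec$radius,
                          rng[1], rng[2], spec$bins)
  shape0 <- dim(pyramid_level(pyr, 0))
  idx <- slab_block_index(slab$z_range, shape0, spec$scale, lr[1],
                          c(lr[2] - lr[1], d[2], d[3]))
  block[, idx, drop = FALSE]
}

#' Uniform rotation-invariant LBP code of a 3x3 patch
#'
#' The 8 ring neighbours are thresholded against the centre (neighbour >=
#' centre gives bit 1, so ties count as 1) and traversed clockwise starting
#' above the centre.  If the circular bit string has at most 2 transitions
#' (a "uniform" pattern) the code is the number of set bits (0..8);
#' otherwise the code is 9.  Exactly 10 codes are possible.
#'
#' @param patch 3x3 numeric matrix; `patch[2, 2]` is the centre.
#' @return integer code in 0..9.
#' @export
lbp_code <- function(patch) {
  stopifnot(is.matrix(patch), all(dim(patch) == c(3, 3)))
  da <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  db <- c(0, 1, 1, 1, 0, -1, -1, -1)
  bits <- as.integer(patch[cbind(2 + da, 2 + db)] >= patch[2, 2])
  trans <- sum(bits != bits[c(2:8, 1)])
  if (trans <= 2L) sum(bits) else 9L
}

lbp_plane_id <- function(plane) {
  match(match.arg(plane, c("xy", "yz", "xz")), c("xy", "yz", "xz")) - 1L
}

#' Per-voxel LBP codes of a volume on one plane
#'
#' @param level 3D array (a pyramid level).
#' @param plane `"xy"`, `"yz"` or `"xz"`.
#' @return integer 3D array of codes in 0..9, same dimensions as `level`.
#' @export
lbp_codes <- function(level, plane = c("xy", "yz", "xz")) {
  level <- as_volume_array(level)
  codes <- cpp_lbp_codes(level, dim(level), lbp_plane_id(plane))
  array(codes, dim = dim(level))
}

#' LBP code histogram over an in-plane neighbourhood
#'
#' @param level 3D array (a pyramid level, at the coordinate's scale).
#' @param coord `(z, y, x)` 0-based coordinate(s) on the level grid.
#' @param plane `"xy"`, `"yz"` or `"xz"`.
#' @param r in-plane neighbourhood radius; counts sum to `(2r+1)^2`.
#' @return `10 x n` integer count matrix.
#' @export
lbp_plane_histogram <- function(level, coord, plane = c("xy", "yz", "xz"),
                                r = 4L) {
  level <- as_volume_array(level)
  p <- lbp_plane_id(plane)
  codes <- cpp_lbp_codes(level, dim(level), p)
  cpp_plane_hist_at(codes, dim(level), as_coord_matrix(coord), p, r)
}

# cache of per-plane code arrays, keyed by "<scale>_<plane>"
codes_for <- function(pyr, s, plane_id, cache = NULL) {
  key <- paste0("s", s, "_p", plane_id)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  level <- pyramid_level(pyr, s)
  codes <- cpp_lbp_codes(level, dim(level), plane_id)
  if (!is.null(cache)) cache[[key]] <- codes
  codes
}

#' Three-orthogonal-plane LBP feature at scale-0 coordinates
#'
#' Concatenation xy, yz, xz of the three 10-bin code histograms at the
#' mapped coordinate on the scale-`s` level; always length 30.
#'
#' @param pyr a [build_pyramid()] result.
#' @param coords scale-0 coordinate(s), vector or n x 3 matrix.
#' @param spec an [lbp_spec()].
#' @param cache optional environment used to memoise per-plane code arrays.
#' @return `30 x n` integer count matrix.
#' @export
lbp_top_feature <- function(pyr, coords, spec, cache = NULL) {
  coords <- as_coord_matrix(coords)
  level <- pyramid_level(pyr, spec$scale)
  d <- dim(level)
  mapped <- clamp_to_level(map_coordinate(coords, spec$scale), d)
  out <- matrix(0L, 30L, nrow(coords))
  for (p in 0:2) {
    codes <- codes_for(pyr, spec$scale, p, cache)
    out[(10 * p + 1):(10 * p + 10), ] <-
      cpp_plane_hist_at(codes, d, mapped, p, spec$radius)
  }
  out
}

feature_colnames <- function(config) {
  c(if (config$include_intensity) "intensity",
    paste0("h1_", seq_len(config$hist1$bins)),
    paste0("h2_", seq_len(config$hist2$bins)),
    paste0("lbp_", rep(c("xy", "yz", "xz"), each = 10), "_", rep(0:9, 3)))
}

#' Compose the full feature matrix for a set of voxels
#'
#' Rows follow the order of `coords`; columns are laid out as
#' `[intensity | hist1 | hist2 | lbp]`.  With `normalise = TRUE` (the
#' default, and what the classifiers consume) histogram blocks are divided
#' by their neighbourhood sizes and the intensity is rescaled to the unit
#' interval by the recorded volume bounds; with `normalise = FALSE` raw
#' counts and the raw intensity are returned.
#'
#' @param pyr a [build_pyramid()] result.
#' @param coords scale-0 `(z, y, x)` coordinates, n x 3 matrix (0-based).
#' @param config a [feature_config()].
#' @param normalise divide histogram blocks by neighbourhood size.
#' @param cache optional environment memoising LBP code arrays.
#' @return n x [feature_length()] numeric matrix with a `row_coords`
#'   attribute.
#' @export
compose_features <- function(pyr, coords, config, normalise = TRUE,
                             cache = NULL) {
  coords <- as_coord_matrix(coords)
  h1 <- histogram_at(pyr, coords, config$hist1)
  h2 <- histogram_at(pyr, coords, config$hist2)
  lb <- lbp_top_feature(pyr, coords, config$lbp, cache)
  level0 <- pyramid_level(pyr, 0)
  intens <- level0[coords[, 1] + dim(level0)[1] *
                     (coords[, 2] + dim(level0)[2] * coords[, 3]) + 1]
  assemble_features(intens, h1, h2, lb, config, normalise,
                    intensity_range(pyr), coords)
}

assemble_features <- function(intens, h1, h2, lb, config, normalise, rng,
                              coords = NULL) {
  if (normalise) {
    h1 <- h1 / (2 * config$hist1$radius + 1)^3
    h2 <- h2 / (2 * config$hist2$radius + 1)^3
    lb <- lb / (2 * config$lbp$radius + 1)^2
    intens <- (intens - rng[1]) / (rng[2] - rng[1])
  }
  blocks <- list(t(h1), t(h2), t(lb))
  if (config$include_intensity)
    blocks <- c(list(matrix(as.numeric(intens), ncol = 1)), blocks)
  out <- do.call(cbind, blocks)
  colnames(out) <- feature_colnames(config)
  attr(out, "row_coords") <- coords
  out
}

# block (whole-slab) feature composition used by segment_volume: identical
# output to compose_features over the same voxels, but every sub-feature is
# computed with the incremental sliding-window path.
compose_features_block <- function(pyr, z_range, config, normalise = TRUE,
                                   cache = NULL) {
  shape0 <- dim(pyramid_level(pyr, 0))
  rng <- intensity_range(pyr)
  hist_block <- function(spec) {
    level <- pyramid_level(pyr, spec$scale)
    d <- dim(level)
    lr <- slab_level_range(z_range, spec$scale, d[1])
    block <- cpp_hist_block(level, d, lr[1], lr[2], spec$radius,
                            rng[1], rng[2], spec$bins)
    idx <- slab_block_index(z_range, shape0, spec$scale, lr[1],
                            c(lr[2] - lr[1], d[2], d[3]))
    block[, idx, drop = FALSE]
  }
  h1 <- hist_block(config$hist1)
  h2 <- hist_block(config$hist2)
  s <- config$lbp$scale
  level <- pyramid_level(pyr, s)
  d <- dim(level)
  lr <- slab_level_range(z_range, s, d[1])
  idx <- slab_block_index(z_range, shape0, s, lr[1],
                          c(lr[2] - lr[1], d[2], d[3]))
  lb <- matrix(0L, 30L, length(idx))
  for (p in 0:2) {
    codes <- codes_for(pyr, s, p, cache)
    pb <- cpp_plane_hist_block(codes, d, lr[1], lr[2], p, config$lbp$radius)
    lb[(10 * p + 1):(10 * p + 10), ] <- pb[, idx, drop = FALSE]
  }
  level0 <- pyramid_level(pyr, 0)
  intens <- as.vector(level0[(z_range[1] + 1L):z_range[2], , , drop = FALSE])
  assemble_features(intens, h1, h2, lb, config, normalise, rng)
}
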