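#' Default blur-width rule for pyramid construction
#'
#' Anti-alias width proportional to the decimation factor: `sigma(s) =
#' 2^(s-1)` voxels on the scale-0 grid for `s >= 1`, and 0 (no blur) at
#' `s = 0`.
#'
#' @param s scale index.
#' @export
default_sigma_rule <- function(s) if (s == 0) 0 else 2^(s - 1)

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))   # truncate at 4 sigma
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

blur3d <- function(data, sigma) {
  if (sigma <= 0) return(data)
  k <- gaussian_kernel(sigma)
  d <- dim(data)
  out <- data
  storage.mode(out) <- "double"
  for (axis in 0:2) out <- cpp_convolve_axis(out, d, axis, k)
  out
}

#' Build a multi-scale pyramid of a volume
#'
#' Level `s` is the scale-0 volume blurred with a 3D Gaussian of width
#' `sigma_rule(s)` (reflect padding, truncated at 4 sigma) and decimated by
#' keeping every `2^s`-th voxel starting at index 0 in each axis.  Level 0
#' is the original data, unblurred.  Blur is always applied to the scale-0
#' data, not cumulatively level-to-level.
#'
#' @param vol a [volume()].
#' @param S_max highest scale (>= 0); every dimension must be >= `2^S_max`.
#' @param sigma_rule function of `s` giving the blur width in scale-0 voxels.
#' @return `vx_pyramid` with fields `levels` (list of 3D double arrays),
#'   `S_max`, `intensity_min`, `intensity_max`.
#' @export
build_pyramid <- function(vol, S_max = 0L, sigma_rule = default_sigma_rule) {
  stopifnot(S_max >= 0L)
  shape <- vol$shape
  small <- shape < 2^S_max
  if (any(small))
    stop("axis ", paste(c("z", "y", "x")[small], collapse = ", "),
         " smaller than 2^S_max = ", 2^S_max)
  data0 <- vol$data
  storage.mode(data0) <- "double"
  levels <- vector("list", S_max + 1L)
  levels[[1]] <- data0
  for (s in seq_len(S_max)) {
    blurred <- blur3d(data0, sigma_rule(s))
    step <- 2^s
    # keep indices 0, 2^s, 2*2^s, ...; level shape is floor(shape / 2^s)
    idx <- lapply(shape, function(n) (seq_len(n %/% step) - 1L) * step + 1L)
    levels[[s + 1]] <- blurred[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  structure(list(levels = levels, S_max = S_max,
                 intensity_min = vol$intensity_min,
                 intensity_max = vol$intensity_max,
                 sigma_rule = sigma_rule),
            class = "vx_pyramid")
}

#' @export
print.vx_pyramid <- function(x, ...) {
  for (s in 0:x$S_max)
    cat(sprintf("scale %d: %s\n", s,
                paste(dim(x$levels[[s + 1]]), collapse = " x ")))
  invisible(x)
}

#' Map a scale-0 coordinate to its coordinate at scale s
#'
#' Each component is floor-divided by `2^s`: a scale-s voxel covers a
#' `2^s`-cube of scale-0 voxels.
#'
#' @param coord integer vector `(z, y, x)` (0-based) or an n x 3 matrix.
#' @param s scale index.
#' @export
map_coordinate <- function(coord, s) {
  if (is.matrix(coord)) {
    matrix(as.integer(coord %/% 2^s), nrow = nrow(coord))
  } else {
    as.integer(coord %/% 2^s)
  }
}

pyramid_level <- function(pyr, s) {
  if (s > pyr$S_max) stop("pyramid has no level ", s, " (S_max = ",
                          pyr$S_max, ")")
  pyr$levels[[s + 1L]]
}
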