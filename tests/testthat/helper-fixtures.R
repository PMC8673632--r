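# Fixtures are generated in code; nothing is read from disk except what a
# test itself writes to a tempdir.

abind_z <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(parts[[1]][1], c(sum(vapply(parts, function(p) dim(p)[1], 0L)),
                                d[2], d[3]))
  z <- 0L
  for (p in parts) {
    out[z + seq_len(dim(p)[1]), , ] <- p
    z <- z + dim(p)[1]
  }
  out
}

rand_volume <- function(shape, seed = 1L, max_val = 1000L) {
  set.seed(seed)
  volume(array(sample.int(max_val, prod(shape), replace = TRUE), dim = shape))
}

all_coords <- function(shape) {
  g <- expand.grid(z = 0:(shape[1] - 1L), y = 0:(shape[2] - 1L),
                   x = 0:(shape[3] - 1L))
  m <- as.matrix(g[order(g$x, g$y, g$z), ])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# brute-force neighbourhood histogram in plain R: clamped (edge-replicated)
# indexing, linear bins over [lo, hi] with end-bin clamping
r_hist_oracle <- function(level, coord, r, lo, hi, k) {
  d <- dim(level)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  vals <- level[cl(coord[1] + 1L + (-r:r), d[1]),
                cl(coord[2] + 1L + (-r:r), d[2]),
                cl(coord[3] + 1L + (-r:r), d[3])]
  b <- pmin(pmax(floor((vals - lo) / (hi - lo) * k), 0), k - 1)
  tabulate(b + 1L, nbins = k)
}

# brute-force LBP plane-code histogram in plain R, built on lbp_code()
r_lbp_plane_oracle <- function(level, coord, plane, r) {
  d <- dim(level)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  ax <- switch(plane, xy = c(2L, 3L), yz = c(1L, 2L), xz = c(1L, 3L))
  code_at <- function(p) {                      # p: 0-based (z, y, x)
    patch <- matrix(0, 3, 3)
    for (da in -1:1) for (db in -1:1) {
      q <- p
      q[ax[1]] <- q[ax[1]] + da
      q[ax[2]] <- q[ax[2]] + db
      patch[da + 2, db + 2] <- level[cl(q[1] + 1L, d[1]),
                                     cl(q[2] + 1L, d[2]),
                                     cl(q[3] + 1L, d[3])]
    }
    lbp_code(patch)
  }
  counts <- integer(10)
  for (da in -r:r) for (db in -r:r) {
    q <- coord
    q[ax[1]] <- min(max(q[ax[1]] + da, 0L), d[ax[1]] - 1L)
    q[ax[2]] <- min(max(q[ax[2]] + db, 0L), d[ax[2]] - 1L)
    counts[code_at(q) + 1L] <- counts[code_at(q) + 1L] + 1L
  }
  counts
}

# 3x3 patch whose ring (clockwise from 12 o'clock) realises the given bits
patch_from_bits <- function(bits) {
  stopifnot(length(bits) == 8)
  da <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  db <- c(0, 1, 1, 1, 0, -1, -1, -1)
  patch <- matrix(0, 3, 3)
  patch[2, 2] <- 0.5
  patch[cbind(2 + da, 2 + db)] <- bits     # 1 >= 0.5 -> bit 1; 0 < 0.5 -> 0
  patch
}

easy_two_texture <- function(shape = c(24L, 24L, 24L), seed = 5L) {
  make_textured_volume(list(
    texture_region("dark",
                   list(type = "halfspace", axis = "y", from = 0,
                        to = shape[2] %/% 2),
                   list(type = "gaussian", mean = 0.3, sd = 0.02)),
    texture_region("bright", list(type = "rest"),
                   list(type = "gaussian", mean = 0.7, sd = 0.02))),
    shape, seed)
}
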