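# Minimal baseline TIFF codec for greyscale volumes.
#
# No TIFF reader is available among the package's allowed dependencies, so
# the subset of baseline TIFF that tomography slice exports actually use is
# implemented here directly: uncompressed, single-sample greyscale, 8- or
# 16-bit unsigned, striped, little- or big-endian on read (always
# little-endian, one strip per page, on write), with multi-page support.
# Anything else (compression, tiles, palettes, RGB) is rejected with an
# explicit error naming the unsupported field.

TIFF_TAGS <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, Photometric = 262L, StripOffsets = 273L,
  SamplesPerPixel = 277L, RowsPerStrip = 278L, StripByteCounts = 279L,
  SampleFormat = 339L
)

tiff_read_entry_values <- function(con, type, count, endian, base) {
  size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, 0L)
  payload <- readBin(con, "raw", n = 4L)  # always consume the value field
  if (size == 0L) return(NULL)  # types we never need (ascii, rational, ...)
  what <- "integer"
  if (size * count <= 4L) {
    vals <- readBin(payload, what, n = count, size = size,
                    signed = size >= 4L, endian = endian)
  } else {
    off <- readBin(payload, "integer", n = 1L, size = 4L, endian = endian)
    here <- seek(con)
    seek(con, base + off)
    vals <- readBin(con, what, n = count, size = size,
                    signed = size >= 4L, endian = endian)
    seek(con, here)
  }
  vals
}

# Reads every page (IFD) of a TIFF file into a list of integer matrices
# (row = y, col = x).
tiff_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  endian <- if (identical(magic[1:2], as.raw(c(0x49, 0x49)))) "little"
            else if (identical(magic[1:2], as.raw(c(0x4d, 0x4d)))) "big"
            else stop("not a TIFF file: ", path)
  ifd_off <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
  pages <- list()
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    n_entries <- readBin(con, "integer", n = 1L, size = 2L,
                         signed = FALSE, endian = endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      tag <- readBin(con, "integer", n = 1L, size = 2L,
                     signed = FALSE, endian = endian)
      type <- readBin(con, "integer", n = 1L, size = 2L,
                      signed = FALSE, endian = endian)
      count <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
      tags[[as.character(tag)]] <-
        tiff_read_entry_values(con, type, count, endian, 0L)
    }
    ifd_off <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
    g <- function(id, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[id]])]]
      if (is.null(v)) default else v
    }
    width <- g("ImageWidth"); height <- g("ImageLength")
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    bits <- g("BitsPerSample", 1L)[1]
    if (!bits %in% c(8L, 16L))
      stop("unsupported TIFF bit depth: ", bits, " (only 8/16-bit greyscale)")
    if (g("Compression", 1L)[1] != 1L)
      stop("unsupported TIFF compression scheme: ", g("Compression")[1],
           " (only uncompressed)")
    if (g("SamplesPerPixel", 1L)[1] != 1L)
      stop("unsupported TIFF samples per pixel: ", g("SamplesPerPixel")[1],
           " (only single-channel greyscale)")
    sf <- g("SampleFormat", 1L)[1]
    if (!sf %in% c(1L))
      stop("unsupported TIFF sample format: ", sf, " (only unsigned integer)")
    offsets <- g("StripOffsets"); counts <- g("StripByteCounts")
    if (is.null(offsets)) stop("TIFF page missing strip offsets")
    size <- bits %/% 8L
    if (is.null(counts)) counts <- width * height * size
    vals <- integer(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      vals <- c(vals, readBin(con, "integer", n = counts[s] %/% size,
                              size = size, signed = FALSE, endian = endian))
    }
    if (length(vals) != width * height)
      stop("TIFF strip data does not match page dimensions")
    m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    attr(m, "bits") <- bits
    pages[[length(pages) + 1L]] <- m
  }
  pages
}

# Writes a list of integer matrices as an uncompressed little-endian
# greyscale TIFF (one IFD per matrix).
tiff_write <- function(pages, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  size <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)
  # header IFD offset placeholder
  writeBin(0L, con, size = 4L, endian = "little")
  offsets <- integer(length(pages))   # pixel-data offset per page
  pos <- 8L
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    vals <- as.integer(t(m))          # row-major strips
    if (any(vals < 0L) || any(vals >= 2^bits))
      stop("pixel values out of range for ", bits, "-bit TIFF")
    offsets[i] <- pos
    if (bits == 8L) {
      writeBin(as.raw(vals), con)
    } else {
      # manual little-endian packing: writeBin size=2 cannot represent
      # unsigned values >= 2^15
      writeBin(as.raw(rbind(vals %% 256L, vals %/% 256L)), con)
    }
    pos <- pos + length(vals) * size
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {  # SHORT packed into 4 bytes
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  ifd_offsets <- integer(length(pages))
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    ifd_offsets[i] <- pos
    n_entries <- 9L
    writeBin(n_entries, con, size = 2L, endian = "little")
    entry(256L, 3L, 1L, ncol(m))                 # ImageWidth
    entry(257L, 3L, 1L, nrow(m))                 # ImageLength
    entry(258L, 3L, 1L, bits)                    # BitsPerSample
    entry(259L, 3L, 1L, 1L)                      # Compression = none
    entry(262L, 3L, 1L, 1L)                      # Photometric = BlackIsZero
    entry(273L, 4L, 1L, offsets[i])              # StripOffsets
    entry(277L, 3L, 1L, 1L)                      # SamplesPerPixel
    entry(278L, 3L, 1L, nrow(m))                 # RowsPerStrip
    entry(279L, 4L, 1L, length(m) * size)        # StripByteCounts
    next_ifd <- if (i < length(pages)) pos + 2L + n_entries * 12L + 4L else 0L
    writeBin(as.integer(next_ifd), con, size = 4L, endian = "little")
    pos <- pos + 2L + n_entries * 12L + 4L
  }
  # patch the first IFD offset in the header
  seek(con, 4L)
  writeBin(ifd_offsets[1], con, size = 4L, endian = "little")
  invisible(path)
}
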