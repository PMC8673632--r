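#' Construct a volume object
#'
#' A volume is a 3D grid of scalar intensities with axis order `(z, y, x)`
#' (z = slice index) and recorded global intensity bounds.  All coordinates
#' in this package are 0-based and z-ranges are half-open, matching the
#' on-disk slice numbering.
#'
#' @param data 3D array, dimension `(nz, ny, nx)`.  Integer (8/16-bit range)
#'   or numeric (typically in the unit interval).
#' @param voxel_size_um optional scalar voxel edge length in micrometres.
#' @param intensity_min,intensity_max recorded global bounds; default the
#'   observed data range.
#' @return An object of class `vx_volume` with fields `data`, `shape`,
#'   `intensity_min`, `intensity_max`, `voxel_size_um`.
#' @export
volume <- function(data, voxel_size_um = NULL,
                   intensity_min = NULL, intensity_max = NULL) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  if (is.null(intensity_min)) intensity_min <- min(data)
  if (is.null(intensity_max)) intensity_max <- max(data)
  if (intensity_min > min(data) || intensity_max < max(data))
    stop("recorded intensity bounds do not cover the data")
  structure(list(data = data, shape = dim(data),
                 intensity_min = intensity_min,
                 intensity_max = intensity_max,
                 voxel_size_um = voxel_size_um),
            class = "vx_volume")
}

#' @export
print.vx_volume <- function(x, ...) {
  cat(sprintf("<vx_volume> %d x %d x %d (z,y,x), range [%g, %g]%s\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$intensity_min, x$intensity_max,
              if (is.null(x$voxel_size_um)) ""
              else sprintf(", voxel %g um", x$voxel_size_um)))
  invisible(x)
}

as_volume_array <- function(x) {
  if (inherits(x, "vx_volume")) x$data else x
}

#' Read a volume from disk
#'
#' Supported formats: a directory of equally-shaped 2D greyscale TIFF slices
#' (lexicographic filename order = z order), a single multi-page TIFF, or an
#' HDF5 dataset.
#'
#' @param path file or directory path.
#' @param format `"auto"` (default; inferred from the path), `"tiff_stack"`,
#'   `"tiff"` or `"hdf5"`.
#' @param dataset HDF5 dataset name (default `"/volume"`).
#' @return A [volume()].
#' @export
read_volume <- function(path, format = c("auto", "tiff_stack", "tiff", "hdf5"),
                        dataset = "/volume") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "tiff_stack"
      else if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
      else "tiff"
  }
  if (format == "hdf5") {
    data <- rhdf5::h5read(path, dataset)
    storage.mode(data) <- if (is.double(data)) "double" else "integer"
    return(volume(data))
  }
  pages <- if (format == "tiff_stack") {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    unlist(lapply(files, tiff_read), recursive = FALSE)
  } else {
    tiff_read(path)
  }
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent slice shapes across TIFF pages/files")
  nz <- length(pages)
  data <- array(0L, dim = c(nz, shapes[1, 1], shapes[2, 1]))
  for (z in seq_len(nz)) data[z, , ] <- pages[[z]]
  volume(data)
}

#' Write a volume to disk
#'
#' @param vol a [volume()] with integer data.
#' @param path output directory (`tiff_stack`), file (`tiff`/`hdf5`).
#' @param format as in [read_volume()]; `"auto"` infers from the path.
#' @param dataset HDF5 dataset name.
#' @param bits TIFF bit depth, 8 or 16.
#' @export
write_volume <- function(vol, path,
                         format = c("auto", "tiff_stack", "tiff", "hdf5"),
                         dataset = "/volume", bits = 16L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
      else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
      else "tiff_stack"
  }
  data <- as_volume_array(vol)
  if (format == "hdf5") {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(data, path, dataset)
    rhdf5::h5closeAll()
    return(invisible(path))
  }
  if (!is.integer(data)) {
    if (max(data) <= 1 && min(data) >= 0) {
      data <- array(as.integer(round(data * (2^bits - 1))), dim = dim(data))
    } else stop("TIFF output requires integer data or unit-interval reals")
  }
  pages <- lapply(seq_len(dim(data)[1]), function(z) data[z, , ])
  if (format == "tiff") {
    tiff_write(pages, path, bits = bits)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (z in seq_along(pages))
      tiff_write(pages[z], file.path(path, sprintf("slice_z%05d.tif", z - 1L)),
                 bits = bits)
  }
  invisible(path)
}

#' Construct a label map
#'
#' Labels get contiguous integer ids `0..N-1` in the order given.  One label
#' is the explicit "anything else" class (`unlabelled`); the sentinel
#' `ignore_id = 255` marks voxels with no manual annotation at all and is
#' never a trainable class.
#'
#' @param names character vector of unique label names, length >= 2.
#' @param unlabelled name of the "anything else" label (default the first).
#' @return `vx_label_map` with fields `names`, `ids`, `unlabelled_id`,
#'   `ignore_id`.
#' @export
label_map <- function(names, unlabelled = names[1]) {
  if (length(names) < 2L) stop("a label map needs at least 2 labels")
  if (anyDuplicated(names)) stop("label names must be unique")
  if (!unlabelled %in% names) stop("unlabelled label not among names")
  if (length(names) >= 255L) stop("at most 254 labels (255 is the ignore id)")
  structure(list(names = names, ids = seq_along(names) - 1L,
                 unlabelled_id = match(unlabelled, names) - 1L,
                 ignore_id = 255L),
            class = "vx_label_map")
}

#' @export
print.vx_label_map <- function(x, ...) {
  cat("<vx_label_map>", paste0(x$ids, "=", x$names, collapse = ", "),
      sprintf("(unlabelled=%d, ignore=%d)\n", x$unlabelled_id, x$ignore_id))
  invisible(x)
}

#' Construct an annotated slice
#'
#' @param slice_index 0-based z position of the slice in the volume.
#' @param labels integer matrix `(ny, nx)` of label ids, with `ignore_id`
#'   (255) where no annotation exists.
#' @param map optional [label_map()] to validate against.
#' @export
annotated_slice <- function(slice_index, labels, map = NULL) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  labels <- matrix(as.integer(labels), nrow = nrow(labels))
  if (!is.null(map)) {
    bad <- setdiff(unique(as.vector(labels)), c(map$ids, map$ignore_id))
    if (length(bad))
      stop("label codes not in label map: ", paste(bad, collapse = ", "))
  }
  structure(list(slice_index = as.integer(slice_index), labels = labels),
            class = "vx_annotated_slice")
}

#' Read annotated label slices
#'
#' Each file is an integer-coded greyscale image (PNG or TIFF) whose pixel
#' values are label ids (255 = ignore).  The z index is parsed from the
#' filename, which must contain `z<digits>` (e.g. `labels_z00042.png`).
#'
#' @param paths character vector of label image files.
#' @param map a [label_map()]; unknown codes are rejected.
#' @param shape optional volume shape `(nz, ny, nx)` to validate against.
#' @return list of [annotated_slice()].
#' @export
read_annotations <- function(paths, map, shape = NULL) {
  lapply(paths, function(p) {
    zm <- regmatches(basename(p), regexpr("z[0-9]+", basename(p)))
    if (length(zm) == 0L)
      stop("cannot parse z index from filename: ", basename(p))
    z <- as.integer(substring(zm, 2))
    labels <- if (grepl("\\.png$", p, ignore.case = TRUE)) {
      img <- png::readPNG(p)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      matrix(as.integer(round(img * 255)), nrow = nrow(img))
    } else {
      m <- tiff_read(p)[[1]]
      matrix(as.integer(m), nrow = nrow(m))
    }
    if (!is.null(shape)) {
      if (z < 0L || z >= shape[1])
        stop("slice index ", z, " outside volume (nz = ", shape[1], ")")
      if (nrow(labels) != shape[2] || ncol(labels) != shape[3])
        stop("label image shape ", nrow(labels), "x", ncol(labels),
             " does not match volume (ny, nx) = ",
             shape[2], "x", shape[3], ": ", basename(p))
    }
    annotated_slice(z, labels, map)
  })
}

#' Write annotated label slices as PNG images
#'
#' @param slices list of [annotated_slice()].
#' @param dir output directory; files are named `labels_z<zzzzz>.png`.
#' @export
write_annotations <- function(slices, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in slices) {
    png::writePNG(s$labels / 255,
                  file.path(dir, sprintf("labels_z%05d.png", s$slice_index)))
  }
  invisible(dir)
}

#' Split a volume into z-slabs with halo
#'
#' The slab z-ranges partition `[0, nz)` exactly; each slab additionally
#' carries `halo` extra slices on each side (clamped at the volume faces) so
#' every in-range voxel has its full neighbourhood available.
#'
#' @param vol a [volume()].
#' @param slab_thickness slices per slab, >= 1.
#' @param halo extra slices loaded on each side.
#' @return list of `vx_slab` objects with fields `z_range` (half-open,
#'   0-based), `halo`, `loaded_range` and `data` (the loaded sub-array).
#' @export
iter_slabs <- function(vol, slab_thickness, halo = 0L) {
  stopifnot(slab_thickness >= 1L, halo >= 0L)
  nz <- vol$shape[1]
  if (halo > nz)
    warning("halo (", halo, ") exceeds volume depth; fully clamped")
  starts <- seq(0L, nz - 1L, by = slab_thickness)
  lapply(starts, function(z0) {
    z1 <- min(z0 + slab_thickness, nz)
    l0 <- max(z0 - halo, 0L)
    l1 <- min(z1 + halo, nz)
    structure(list(z_range = c(z0, z1), halo = halo,
                   loaded_range = c(l0, l1),
                   data = vol$data[(l0 + 1L):l1, , , drop = FALSE]),
              class = "vx_slab")
  })
}
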