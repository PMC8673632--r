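#' Split annotated slices into train / validation / test sets
#'
#' Assignment is random by slice (never by voxel).  Set sizes follow
#' largest-remainder apportionment of the fractions, with remainder ties
#' resolved toward the earlier set (train before validation before test).
#'
#' @param annotated list of [annotated_slice()] objects, or an integer
#'   vector of slice indices.
#' @param fractions length-3 fractions summing to 1 (default 0.6/0.2/0.2).
#' @param seed RNG seed.
#' @return `vx_slice_split`: list with `train`, `validation`, `test` slice
#'   index vectors.
#' @export
split_slices <- function(annotated, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  idx <- if (is.numeric(annotated)) as.integer(annotated)
         else vapply(annotated, function(s) s$slice_index, 0L)
  n <- length(idx)
  if (n < 3L) stop("need at least 3 annotated slices to split")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  quota <- n * fractions
  sizes <- floor(quota)
  short <- n - sum(sizes)
  if (short > 0) {
    # largest remainder; ties to the earlier set (stable order)
    order_rem <- order(-(quota - sizes), seq_along(quota))
    sizes[order_rem[seq_len(short)]] <- sizes[order_rem[seq_len(short)]] + 1L
  }
  set.seed(seed)
  perm <- sample(idx)
  structure(list(train = sort(perm[seq_len(sizes[1])]),
                 validation = sort(perm[sizes[1] + seq_len(sizes[2])]),
                 test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]),
                 fractions = fractions, seed = seed),
            class = "vx_slice_split")
}

#' Sample voxels per label from annotated slices
#'
#' Draws `min(per_label_n, available)` voxels per label, uniformly without
#' replacement; voxels carrying the ignore sentinel are never sampled.
#'
#' @param slices list of [annotated_slice()].
#' @param per_label_n target number per label (`Inf` = all).
#' @param seed RNG seed.
#' @param map optional [label_map()]; if given, every id in the map must be
#'   present in the slices (error listing missing labels otherwise).
#' @param ignore_id sentinel for unannotated voxels (default 255).
#' @return list with `coords` (n x 3 matrix of 0-based `(z, y, x)`) and
#'   `labels` (0-based integer ids).
#' @export
sample_voxels <- function(slices, per_label_n = 16000L, seed = 1L,
                          map = NULL, ignore_id = 255L) {
  stopifnot(per_label_n >= 1)
  coords <- list(); labels <- list()
  for (s in slices) {
    keep <- which(s$labels != ignore_id)
    if (length(keep) == 0L) next
    ny <- nrow(s$labels)
    coords[[length(coords) + 1L]] <-
      cbind(s$slice_index, (keep - 1L) %% ny, (keep - 1L) %/% ny)
    labels[[length(labels) + 1L]] <- s$labels[keep]
  }
  coords <- do.call(rbind, coords)
  labels <- unlist(labels)
  if (is.null(coords)) stop("no labelled voxels in the given slices")
  if (!is.null(map)) {
    missing <- setdiff(map$ids, unique(labels))
    if (length(missing))
      stop("labels absent from all slices: ",
           paste(map$names[missing + 1L], collapse = ", "))
  }
  set.seed(seed)
  picked <- unlist(lapply(sort(unique(labels)), function(lb) {
    ix <- which(labels == lb)
    if (length(ix) <= per_label_n) ix else sample(ix, per_label_n)
  }))
  storage.mode(coords) <- "integer"
  list(coords = coords[picked, , drop = FALSE], labels = labels[picked])
}

pyramid_scale_needed <- function(config) {
  max(config$hist2$scale, config$lbp$scale)
}

#' Train the end-to-end segmenter
#'
#' Splits the annotated slices 60/20/20 (by slice), optionally runs the
#' two-stage hyperparameter search on the training and validation sets, and
#' trains the final classifier on the full training set (optionally capped
#' per label), bundling the feature configuration, label map and intensity
#' bounds into the returned model.
#'
#' @param vol a [volume()].
#' @param annotations list of [annotated_slice()].
#' @param map a [label_map()].
#' @param config either a list with `features` (a [feature_config()]) and
#'   `classifier` (an [rf_spec()]/[nn_spec()]), e.g. from [preset_config()],
#'   or a list with `space` (a [search_space()]) and `budget` (a
#'   [search_budget()]) to optimise first.
#' @param seed RNG seed for the split, sampling and model fit.
#' @param per_label_n cap on final-training voxels per label (`Inf` = all).
#' @param fractions slice split fractions.
#' @return a `vx_model` with the slice split in `$split` and, when a search
#'   ran, its result in `$search`.
#' @export
train_pipeline <- function(vol, annotations, map, config, seed = 1L,
                           per_label_n = 16000L,
                           fractions = c(0.6, 0.2, 0.2)) {
  split <- split_slices(annotations, fractions, seed)
  slice_of <- function(ix) Filter(function(s) s$slice_index %in% ix,
                                  annotations)
  search_result <- NULL
  if (!is.null(config$space)) {
    tr_vox <- sample_voxels(slice_of(split$train), Inf, seed, map)
    va_vox <- sample_voxels(slice_of(split$validation), Inf, seed, map)
    pyr <- build_pyramid(vol, 2L)
    search_result <- two_stage_search(
      list(pyramid = pyr, coords = tr_vox$coords, labels = tr_vox$labels),
      list(pyramid = pyr, coords = va_vox$coords, labels = va_vox$labels),
      config$space, config$budget)
    features <- config_to_feature_config(search_result$best_config)
    classifier <- config_to_model_spec(search_result$best_config,
                                       config$space$classifier, seed)
  } else {
    features <- config$features
    classifier <- config$classifier
  }
  pyr <- build_pyramid(vol, pyramid_scale_needed(features))
  vox <- sample_voxels(slice_of(split$train), per_label_n, seed, map)
  X <- compose_features(pyr, vox$coords, features)
  model <- train_classifier(classifier, X, vox$labels, map = map,
                            feature_config = features,
                            intensity_bounds = c(vol$intensity_min,
                                                 vol$intensity_max))
  model$split <- split
  model$search <- search_result
  model
}

#' Segment a whole volume slab by slab
#'
#' Labels every voxel using the model's feature configuration and
#' classifier.  The volume is processed in z-slabs: per-voxel features and
#' predictions are only ever materialised for one slab, and the output is
#' identical for any slab thickness.
#'
#' @param model a `vx_model` carrying a feature configuration.
#' @param vol a [volume()].
#' @param slab_thickness slices per slab.
#' @return integer 3D array of 0-based label ids, same shape as the volume.
#' @export
segment_volume <- function(model, vol, slab_thickness = 16L) {
  config <- model$feature_config
  if (is.null(config)) stop("model carries no feature configuration")
  pyr <- build_pyramid(vol, pyramid_scale_needed(config))
  if (!is.null(model$intensity_bounds)) {
    # inference must bin intensities exactly as training did
    pyr$intensity_min <- model$intensity_bounds[1]
    pyr$intensity_max <- model$intensity_bounds[2]
  }
  nz <- vol$shape[1]
  out <- array(NA_integer_, dim = vol$shape)
  cache <- new.env(parent = emptyenv())
  for (z0 in seq(0L, nz - 1L, by = slab_thickness)) {
    z1 <- min(z0 + slab_thickness, nz)
    X <- compose_features_block(pyr, c(z0, z1), config, cache = cache)
    pred <- predict_labels(model, X)
    out[(z0 + 1L):z1, , ] <- array(pred, dim = c(z1 - z0, vol$shape[2],
                                                 vol$shape[3]))
  }
  out
}

#' Evaluate a predicted labelling against annotated truth slices
#'
#' Computes, over the non-ignore voxels of the truth slices: the per-label
#' intersection-over-union (as percentages; `NA` for labels absent from
#' both truth and prediction), the overall voxel accuracy, the micro-
#' averaged IoU, the N x N confusion matrix (rows = truth) and each label's
#' share of the evaluated voxels.
#'
#' @param predicted integer label array from [segment_volume()] (or a
#'   matching 3D array).
#' @param truth_slices list of [annotated_slice()] (e.g. the test slices).
#' @param map a [label_map()].
#' @return `vx_evaluation_report`.
#' @export
evaluate <- function(predicted, truth_slices, map) {
  n <- length(map$ids)
  confusion <- matrix(0, n, n, dimnames = list(truth = map$names,
                                               predicted = map$names))
  for (s in truth_slices) {
    z <- s$slice_index
    if (z < 0L || z >= dim(predicted)[1])
      stop("truth slice ", z, " outside predicted volume")
    keep <- s$labels != map$ignore_id
    if (!any(keep)) next
    truth <- s$labels[keep]
    pred <- predicted[z + 1L, , ][keep]
    confusion <- confusion + unclass(table(factor(truth, levels = map$ids),
                                           factor(pred, levels = map$ids)))
  }
  dimnames(confusion) <- list(truth = map$names, predicted = map$names)
  total <- sum(confusion)
  if (total == 0) stop("no labelled voxels in the truth slices")
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  union <- tp + fp + fn
  iou <- ifelse(union > 0, 100 * tp / union, NA_real_)
  structure(list(
    per_label_iou = stats::setNames(iou, map$names),
    overall_accuracy = 100 * sum(tp) / total,
    overall_micro_iou = 100 * sum(tp) / (2 * total - sum(tp)),
    confusion = confusion,
    label_share = rowSums(confusion) / total,
    n_voxels = total), class = "vx_evaluation_report")
}

#' @export
print.vx_evaluation_report <- function(x, ...) {
  cat(sprintf("<vx_evaluation_report> %d voxels\n", x$n_voxels))
  for (nm in names(x$per_label_iou)) {
    v <- x$per_label_iou[[nm]]
    cat(sprintf("  IoU %-14s %s  (share %5.1f%%)\n", nm,
                if (is.na(v)) "   --" else sprintf("%5.1f%%", v),
                100 * x$label_share[[nm]]))
  }
  cat(sprintf("  overall accuracy  %5.1f%%\n", x$overall_accuracy))
  cat(sprintf("  overall micro-IoU %5.1f%%\n", x$overall_micro_iou))
  invisible(x)
}
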