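#' Random forest specification
#'
#' Fixed settings: Gini impurity splits, maximum tree depth 16, no limit on
#' leaf count, number of features per split equal to the square root of the
#' total feature count, bootstrap resampling.  The number of trees is the
#' only tunable and is restricted to \{16, 32, 64\}.
#'
#' @param n_trees one of 16, 32, 64.
#' @param seed RNG seed used when fitting.
#' @export
rf_spec <- function(n_trees = 64L, seed = 1L) {
  if (!n_trees %in% c(16L, 32L, 64L))
    stop("n_trees must be one of 16, 32, 64")
  structure(list(kind = "rf", n_trees = as.integer(n_trees),
                 max_depth = 16L, seed = as.integer(seed)),
            class = c("vx_rf_spec", "vx_model_spec"))
}

#' Neural network specification
#'
#' A feed-forward network with two hidden layers and leaky-ReLU activations
#' (negative slope 0.01), softmax output trained with cross-entropy and the
#' Adam optimiser (learning rate 1e-3), dropout on the hidden layers, weight
#' initialisation from N(0, `init_stddev`^2), zero bias initialisation, and
#' early stopping (patience 5, best weights restored, at most 100 epochs).
#'
#' @param layer1,layer2 hidden layer sizes, each one of 32, 64, 128, 256.
#' @param dropout dropout rate in [0, 0.5].
#' @param init_stddev weight init standard deviation in [0.0001, 1].
#' @param minibatch one of 4, 8, 16, 32, 64.
#' @param seed RNG seed used when fitting.
#' @export
nn_spec <- function(layer1 = 64L, layer2 = 64L, dropout = 0.25,
                    init_stddev = 0.05, minibatch = 32L, seed = 1L) {
  sizes <- c(32L, 64L, 128L, 256L)
  if (!layer1 %in% sizes || !layer2 %in% sizes)
    stop("layer sizes must be one of 32, 64, 128, 256")
  if (dropout < 0 || dropout > 0.5) stop("dropout must be in [0, 0.5]")
  if (init_stddev < 1e-4 || init_stddev > 1)
    stop("init_stddev must be in [0.0001, 1]")
  if (!minibatch %in% c(4L, 8L, 16L, 32L, 64L))
    stop("minibatch must be one of 4, 8, 16, 32, 64")
  structure(list(kind = "nn", layer1 = as.integer(layer1),
                 layer2 = as.integer(layer2), dropout = dropout,
                 init_stddev = init_stddev, minibatch = as.integer(minibatch),
                 seed = as.integer(seed)),
            class = c("vx_nn_spec", "vx_model_spec"))
}

#' Train a classifier on a feature matrix
#'
#' @param spec an [rf_spec()] or [nn_spec()].
#' @param features numeric matrix, one row per voxel.
#' @param labels integer label ids (0-based), one per row.
#' @param map optional [label_map()] stored in the model.
#' @param feature_config optional [feature_config()] stored in the model.
#' @param intensity_bounds optional `c(min, max)` of the training volume,
#'   stored so inference normalises identically.
#' @param n_classes number of classes; default from `map` or
#'   `max(labels) + 1`.
#' @return a `vx_model`; retraining with the same seed on identical data
#'   yields identical predictions.
#' @export
train_classifier <- function(spec, features, labels, map = NULL,
                             feature_config = NULL, intensity_bounds = NULL,
                             n_classes = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) == 0L) stop("cannot train on an empty feature matrix")
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length")
  if (any(!is.finite(features))) stop("features contain non-finite values")
  if (is.null(n_classes))
    n_classes <- if (!is.null(map)) length(map$ids) else max(labels) + 1L
  if (any(labels < 0L | labels >= n_classes))
    stop("labels outside 0..", n_classes - 1L)
  set.seed(spec$seed)
  fit <- if (spec$kind == "rf") {
    mtry <- max(1L, as.integer(floor(sqrt(ncol(features)))))
    cpp_rf_train(features, labels, n_classes, spec$n_trees,
                 spec$max_depth, mtry, 2L)
  } else {
    mlp_fit(features, labels, n_classes, spec)
  }
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 n_classes = as.integer(n_classes), n_features = ncol(features),
                 label_map = map, feature_config = feature_config,
                 intensity_bounds = intensity_bounds,
                 meta = list(n_train = nrow(features), seed = spec$seed)),
            class = "vx_model")
}

#' @export
print.vx_model <- function(x, ...) {
  cat(sprintf("<vx_model> %s, %d classes, %d features, trained on %d voxels\n",
              x$kind, x$n_classes, x$n_features, x$meta$n_train))
  invisible(x)
}

check_feature_width <- function(model, features) {
  if (ncol(features) != model$n_features)
    stop("feature width ", ncol(features), " does not match model (expected ",
         model$n_features, ")")
}

#' Per-class scores for a feature matrix
#'
#' Rows are non-negative and sum to 1.  For the random forest this is the
#' average of per-tree leaf class distributions; for the neural network the
#' softmax output.
#'
#' @param model a `vx_model`.
#' @param features numeric matrix with [train_classifier()]'s feature width.
#' @return n x N numeric matrix.
#' @export
predict_proba <- function(model, features) {
  features <- as.matrix(features)
  check_feature_width(model, features)
  p <- if (model$kind == "rf") {
    cpp_rf_proba(model$fit, features, model$n_classes)
  } else {
    mlp_proba(model$fit, features)
  }
  if (!is.null(model$label_map)) colnames(p) <- model$label_map$names
  p
}

#' Predicted label ids for a feature matrix
#'
#' The argmax of [predict_proba()]; exact score ties break toward the lowest
#' label id.
#'
#' @inheritParams predict_proba
#' @return integer vector of 0-based label ids.
#' @export
predict_labels <- function(model, features) {
  p <- predict_proba(model, features)
  max.col(p, ties.method = "first") - 1L
}

#' Save a trained model bundle
#'
#' Writes a directory holding a JSON manifest (classifier kind and
#' hyperparameters, feature configuration, label map, intensity bounds,
#' seeds, package version) and the serialised classifier state.
#'
#' @param model a `vx_model`.
#' @param dir output directory (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    version = as.character(utils::packageVersion("voxelseg")),
    kind = model$kind,
    spec = unclass(model$spec),
    n_classes = model$n_classes,
    n_features = model$n_features,
    label_map = if (!is.null(model$label_map)) unclass(model$label_map),
    feature_config = if (!is.null(model$feature_config))
      lapply(unclass(model$feature_config),
             function(p) if (is.list(p)) unclass(p) else p),
    intensity_bounds = model$intensity_bounds,
    meta = model$meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(model$fit, file.path(dir, "classifier.rds"))
  invisible(dir)
}

#' Load a model bundle written by [save_model()]
#' @param dir bundle directory.
#' @return a `vx_model`; random-forest predictions are bit-identical to the
#'   model that was saved.
#' @export
load_model <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  spec <- if (m$kind == "rf") {
    rf_spec(m$spec$n_trees, m$spec$seed)
  } else {
    nn_spec(m$spec$layer1, m$spec$layer2, m$spec$dropout,
            m$spec$init_stddev, m$spec$minibatch, m$spec$seed)
  }
  map <- if (!is.null(m$label_map))
    label_map(m$label_map$names,
              m$label_map$names[m$label_map$unlabelled_id + 1L])
  fc <- if (!is.null(m$feature_config))
    feature_config(
      histogram_spec(m$feature_config$hist1$radius, 0L,
                     m$feature_config$hist1$bins),
      histogram_spec(m$feature_config$hist2$radius,
                     m$feature_config$hist2$scale,
                     m$feature_config$hist2$bins),
      lbp_spec(m$feature_config$lbp$scale, m$feature_config$lbp$radius),
      m$feature_config$include_intensity)
  structure(list(kind = m$kind, spec = spec,
                 fit = readRDS(file.path(dir, "classifier.rds")),
                 n_classes = m$n_classes, n_features = m$n_features,
                 label_map = map, feature_config = fc,
                 intensity_bounds = m$intensity_bounds,
                 meta = m$meta),
            class = "vx_model")
}

#' Maximum depth over the fitted trees of a random-forest model
#' @param model a `vx_model` of kind `"rf"`.
#' @export
rf_fitted_depth <- function(model) {
  stopifnot(model$kind == "rf")
  cpp_rf_max_depth(model$fit)
}
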