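# Two-stage random hyperparameter search over the joint feature-selection /
# classifier space: a global phase drawing uniform random configurations,
# then a local phase mutating one variable at a time from the best found
# (stochastic hill climbing).  Visited configurations are never
# re-evaluated; a phase exits early once `t` seconds pass inside the
# novelty-search loop without an unvisited configuration turning up.

#' The search space of feature and classifier variables
#'
#' Feature block: hist1 radius 1-8, bins \{8,16,32\}; hist2 scale 0-2,
#' radius 1-32, bins \{8,16,32\}; LBP scale 0-2, radius 1-32.  Classifier
#' block: forest trees \{16,32,64\}, or the neural-network ranges (layer
#' sizes \{32,64,128,256\}, dropout 0-0.5, init stddev 1e-4-1, minibatch
#' \{4,8,16,32,64\}).  Continuous variables are discretised so that the
#' visited-set test of the search is meaningful: dropout on a 0.05-step
#' grid, init stddev on a 16-point log-spaced grid (its range spans four
#' decades).
#'
#' @param classifier `"rf"` or `"nn"`.
#' @return a `vx_search_space`: named list of admissible value vectors.
#' @export
search_space <- function(classifier = c("rf", "nn")) {
  classifier <- match.arg(classifier)
  vars <- list(
    h1_radius = 1:8,
    h1_bins = c(8L, 16L, 32L),
    h2_scale = 0:2,
    h2_radius = 1:32,
    h2_bins = c(8L, 16L, 32L),
    lbp_scale = 0:2,
    lbp_radius = 1:32)
  vars <- c(vars, if (classifier == "rf") {
    list(n_trees = c(16L, 32L, 64L))
  } else {
    list(layer1 = c(32L, 64L, 128L, 256L),
         layer2 = c(32L, 64L, 128L, 256L),
         dropout = seq(0, 0.5, by = 0.05),
         init_stddev = 10^seq(log10(1e-4), log10(1), length.out = 16),
         minibatch = c(4L, 8L, 16L, 32L, 64L))
  })
  structure(list(classifier = classifier, vars = vars),
            class = "vx_search_space")
}

#' Search budget (iterations, sample sizes, novelty timeout)
#'
#' Defaults are the full-scale budget: 1000 global iterations, 10000 local
#' iterations, 16000 training and validation voxels sampled per label, and
#' a 5-second timeout on the search for a not-yet-visited configuration.
#'
#' @param I_g global iterations.
#' @param I_l local iterations.
#' @param S_t training voxels sampled per label.
#' @param S_v validation voxels sampled per label.
#' @param t novelty timeout in seconds.
#' @param seed RNG seed for the whole search.
#' @export
search_budget <- function(I_g = 1000L, I_l = 10000L, S_t = 16000L,
                          S_v = 16000L, t = 5, seed = 1L) {
  stopifnot(I_g > 0, I_l > 0, S_t > 0, S_v > 0, t > 0)
  structure(list(I_g = as.integer(I_g), I_l = as.integer(I_l),
                 S_t = as.integer(S_t), S_v = as.integer(S_v),
                 t = t, seed = as.integer(seed)),
            class = "vx_search_budget")
}

#' Draw a configuration uniformly from the search space
#'
#' Every variable is drawn independently and uniformly from its admissible
#' values.  Uses R's RNG; seed with `set.seed()` for reproducibility.
#'
#' @param space a [search_space()].
#' @return named list of variable values.
#' @export
sample_config <- function(space) {
  lapply(space$vars, function(v) v[sample.int(length(v), 1L)])
}

#' Mutate exactly one variable of a configuration
#'
#' The variable is chosen uniformly; its new value is drawn uniformly from
#' the variable's admissible values excluding the current one, so the result
#' differs from the input in exactly one variable.  A variable whose range
#' is a singleton cannot change; if all variables are singletons the input
#' is returned unchanged.
#'
#' @param config a configuration from [sample_config()].
#' @param space a [search_space()].
#' @export
mutate_config <- function(config, space) {
  nm <- names(space$vars)[sample.int(length(space$vars), 1L)]
  pool <- space$vars[[nm]]
  pool <- pool[pool != config[[nm]]]
  if (length(pool) == 0L) return(config)   # singleton variable
  config[[nm]] <- pool[sample.int(length(pool), 1L)]
  config
}

config_key <- function(config) {
  paste(vapply(config, function(v) format(v, digits = 17), ""),
        collapse = "|")
}

#' Feature configuration encoded by a search-space configuration
#' @param config named list with the `h1_*`, `h2_*`, `lbp_*` variables.
#' @export
config_to_feature_config <- function(config) {
  feature_config(
    hist1 = histogram_spec(config$h1_radius, 0L, config$h1_bins),
    hist2 = histogram_spec(config$h2_radius, config$h2_scale, config$h2_bins),
    lbp = lbp_spec(config$lbp_scale, config$lbp_radius))
}

#' Classifier specification encoded by a search-space configuration
#' @param config a configuration.
#' @param classifier `"rf"` or `"nn"`.
#' @param seed model seed.
#' @export
config_to_model_spec <- function(config, classifier, seed = 1L) {
  if (classifier == "rf") {
    rf_spec(config$n_trees, seed)
  } else {
    nn_spec(config$layer1, config$layer2, config$dropout,
            config$init_stddev, config$minibatch, seed)
  }
}

validate_config <- function(config, space) {
  ok <- vapply(names(space$vars), function(nm) {
    !is.null(config[[nm]]) &&
      any(abs(space$vars[[nm]] - config[[nm]]) < 1e-12)
  }, TRUE)
  all(ok)
}

# balanced per-label sample without replacement; errors on empty labels
balanced_sample <- function(coords, labels, per_label, all_labels) {
  picked <- integer(0)
  for (lb in all_labels) {
    ix <- which(labels == lb)
    if (length(ix) == 0L)
      stop("label ", lb, " has no voxels in the provided set")
    picked <- c(picked, if (length(ix) <= per_label) ix
                        else sample(ix, per_label))
  }
  list(coords = coords[picked, , drop = FALSE], labels = labels[picked])
}

#' Two-stage random search (global sampling, then local mutation)
#'
#' `train_set` and `val_set` are lists with fields `pyramid` (a
#' [build_pyramid()] result), `coords` (n x 3 scale-0 voxel coordinates) and
#' `labels` (0-based ids).  Balanced samples of `S_t` / `S_v` voxels per
#' label are drawn once up front; each candidate configuration is trained on
#' the sampled training voxels and scored by plain accuracy on the sampled
#' validation voxels (balanced sampling makes plain accuracy label-fair).
#' Already-visited configurations are skipped; if `t` seconds elapse while
#' hunting for a novel configuration the phase terminates.  Strict
#' improvement is required to replace the incumbent, so accuracy ties keep
#' the earlier configuration.
#'
#' @param train_set,val_set voxel sets as described above.
#' @param space a [search_space()].
#' @param budget a [search_budget()].
#' @param clock function returning elapsed seconds (injectable for tests);
#'   default the process clock.
#' @return `vx_search_result`: `best_config`, `best_accuracy`, `trace`
#'   (data frame with per-iteration phase, accuracy, best-so-far and the
#'   flattened configuration), `n_visited`.
#' @export
two_stage_search <- function(train_set, val_set, space, budget,
                             clock = function() as.numeric(proc.time()[3])) {
  set.seed(budget$seed)
  all_labels <- sort(unique(c(train_set$labels, val_set$labels)))
  tr <- balanced_sample(train_set$coords, train_set$labels, budget$S_t,
                        all_labels)
  va <- balanced_sample(val_set$coords, val_set$labels, budget$S_v,
                        all_labels)
  n_classes <- max(all_labels) + 1L
  cache_tr <- new.env(parent = emptyenv())
  cache_va <- new.env(parent = emptyenv())

  evaluate_config <- function(config) {
    fc <- config_to_feature_config(config)
    ms <- config_to_model_spec(config, space$classifier, budget$seed)
    Xtr <- compose_features(train_set$pyramid, tr$coords, fc,
                            cache = cache_tr)
    model <- train_classifier(ms, Xtr, tr$labels, n_classes = n_classes)
    Xva <- compose_features(val_set$pyramid, va$coords, fc, cache = cache_va)
    mean(predict_labels(model, Xva) == va$labels)
  }

  visited <- new.env(parent = emptyenv())
  trace <- list()
  best_config <- NULL
  best_acc <- 0

  run_phase <- function(phase, n_iter, propose) {
    for (i in seq_len(n_iter)) {
      hunt_start <- clock()
      config <- NULL
      repeat {
        cand <- propose()
        if (clock() - hunt_start > budget$t) return(invisible(NULL))
        if (is.null(visited[[config_key(cand)]])) { config <- cand; break }
      }
      visited[[config_key(config)]] <- TRUE
      acc <- evaluate_config(config)
      if (acc > best_acc) {          # strict: ties keep the earlier config
        best_acc <<- acc
        best_config <<- config
      }
      trace[[length(trace) + 1L]] <<- c(
        list(phase = phase, accuracy = acc, best_so_far = best_acc), config)
    }
    invisible(NULL)
  }

  run_phase("global", budget$I_g, function() sample_config(space))
  if (is.null(best_config))
    stop("global phase evaluated no configuration (timeout too tight?)")
  run_phase("local", budget$I_l, function() mutate_config(best_config, space))

  trace_df <- do.call(rbind, lapply(trace, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  trace_df$iteration <- seq_len(nrow(trace_df))
  structure(list(best_config = best_config, best_accuracy = best_acc,
                 trace = trace_df,
                 n_visited = length(ls(visited))),
            class = "vx_search_result")
}

#' @export
print.vx_search_result <- function(x, ...) {
  cat(sprintf("<vx_search_result> %d configs evaluated, best accuracy %.4f\n",
              nrow(x$trace), x$best_accuracy))
  invisible(x)
}

#' Write a search trace to CSV
#' @param result a `vx_search_result`.
#' @param path output CSV path.
#' @export
write_search_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
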