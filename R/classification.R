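#' Random-forest classifier configuration
#'
#' Defaults follow the operational setup: 100 trees, 2 randomly selected
#' features per split node, Gini impurity for split selection, balanced
#' training (50 points per class by design of the sampling, not by
#' weighting).
#'
#' @param n_trees number of trees (>= 1), default 100.
#' @param n_random_features features sampled per split, default 2.
#' @param split_criterion only `"gini"` is implemented.
#' @param rng_seed seed for bootstraps / feature sampling, default 42.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100L, n_random_features = 2L,
                      split_criterion = "gini", rng_seed = 42L) {
  split_criterion <- match.arg(split_criterion, "gini")
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 n_random_features = as.integer(n_random_features),
                 split_criterion = split_criterion,
                 rng_seed = as.integer(rng_seed)),
            class = "rf_config")
}

#' Extract per-point band features from a bottom-reflectance scene
#'
#' One row per usable ground-truth point: the scene's band values at the
#' point's pixel plus the class label. Points falling on masked or
#' out-of-grid pixels are dropped, with the count recorded in attribute
#' `n_dropped`.
#'
#' @param scene a [reflectance_scene()], normally stage `"bottom_Rb"`.
#' @param points data.frame with columns `x`, `y`, `class`.
#' @return data.frame with one column per band (`b<nm>`) plus `class`.
#' @export
extract_features <- function(scene, points) {
  rc <- lookup_cells(scene$grid, points$x, points$y)
  ok <- !is.na(rc[, 1])
  ok[ok] <- !scene$mask[rc[ok, , drop = FALSE]]
  if (!any(ok)) stop("no ground-truth points fall on unmasked pixels")
  feat <- vapply(seq_along(scene$bands),
                 function(k) scene$values[, , k][rc[ok, , drop = FALSE]],
                 numeric(sum(ok)))
  feat <- matrix(feat, nrow = sum(ok))
  colnames(feat) <- paste0("b", scene$bands)
  out <- as.data.frame(feat)
  out$class <- as.integer(points$class[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Train the benthic random-forest classifier
#'
#' Thin wrapper over [rf_train()] using an [rf_config()]. Training rows are
#' first sorted into a canonical order (by label, then feature values) so
#' that the result is invariant to the ordering of the input points; with
#' that normalization, a fixed `(data, seed)` pair always yields the same
#' forest.
#'
#' @param features data.frame from [extract_features()] (band columns +
#'   `class`), or a numeric matrix if `labels` is given.
#' @param labels optional integer labels (when `features` has no `class`).
#' @param config an [rf_config()].
#' @return an `rf_model` (see [rf_train()]).
#' @export
train_classifier <- function(features, labels = NULL, config = rf_config()) {
  if (is.data.frame(features) && "class" %in% names(features)) {
    labels <- features$class
    features <- features[setdiff(names(features), "class")]
  }
  if (is.null(labels)) stop("labels required")
  x <- as.matrix(features)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("training data must contain >= 2 classes")
  ord <- do.call(order, c(list(y), lapply(seq_len(ncol(x)), function(j) x[, j])))
  rf_train(x[ord, , drop = FALSE], y[ord],
           n_trees = config$n_trees, mtry = config$n_random_features,
           seed = config$rng_seed)
}

#' Classify a scene into a habitat map
#'
#' Applies the forest to every unmasked pixel; masked pixels get code 0.
#'
#' @param model an `rf_model` trained on the scene's band set.
#' @param scene a [reflectance_scene()] (stage `"bottom_Rb"`).
#' @return a [habitat_map()].
#' @export
classify_scene <- function(model, scene) {
  if (!is.null(model$feature_names) &&
      !identical(model$feature_names, paste0("b", scene$bands)))
    stop("band mismatch: model trained on ",
         paste(model$feature_names, collapse = ","), " but scene has ",
         paste(paste0("b", scene$bands), collapse = ","))
  labels <- matrix(0L, scene$grid$rows, scene$grid$cols)
  use <- which(!scene$mask)
  if (length(use)) {
    x <- vapply(seq_along(scene$bands),
                function(k) scene$values[, , k][use], numeric(length(use)))
    x <- matrix(x, nrow = length(use))
    labels[use] <- rf_predict(model, x)
  }
  habitat_map(labels, scene$grid)
}
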