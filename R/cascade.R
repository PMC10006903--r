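# The two-layer cascade and the flat baseline.
#
# Layer 1 predicts the activity-intensity category from the full training
# set; layer 2 holds one activity-type classifier per intensity, each fitted
# only on the training instances of its intensity (true intensity labels, as
# the training procedure prescribes). At prediction time an instance is
# routed to the layer-2 classifier selected by the layer-1 output, so every
# returned (intensity, activity) pair is taxonomy-consistent by
# construction: a layer-2 classifier can only emit activities of its own
# intensity. Normalisation state and per-node random feature subsets are
# fitted on training data only.

# Ventilation-derived feature indices (used when layer 1 is restricted to
# the respiratory characteristics).
.vent_feature_idx <- function(manifest) {
  grep("^vent_", manifest$names)
}

.check_train_table <- function(train) {
  needed <- c("subject_id", "activity", "intensity")
  missing <- setdiff(needed, names(train))
  if (length(missing) > 0) {
    stop("training table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(train) < 1) stop("training set is empty")
  bad <- train$intensity != intensity_of(train$activity)
  if (any(bad)) stop("intensity labels inconsistent with the taxonomy")
  counts <- table(train$intensity)
  if (any(counts < 2)) {
    stop("intensity category with fewer than 2 training instances: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  invisible(train)
}

# Shared per-node training: draw the feature subset, build the learner,
# fit on the normalised training block.
.fit_node <- function(xn, y, spec, fraction, nseed) {
  subset <- subsample_features(ncol(xn), fraction, seed = nseed)
  learner <- base_learner_factory(spec, seed = nseed)
  model <- learner$fit(xn[, subset, drop = FALSE], y)
  list(model = model, subset = subset, learner = learner)
}

#' Train the two-layer cascade classifier
#'
#' @param train Feature table (rows = window instances) with `subject_id`,
#'   `activity`, `intensity` and the 64 raw feature columns.
#' @param spec A [base_learner_spec()]; default from `config`.
#' @param config A [ccm_config()].
#' @param seed Integer seed driving the per-node feature subsets and any
#'   stochastic learner.
#' @return A fitted `ccm_model`.
#' @export
train_ccm <- function(train, spec = NULL, config = ccm_config(), seed = 1L) {
  .check_train_table(train)
  if (is.null(spec)) spec <- learner_spec_from_config(config)
  manifest <- config_manifest(config)
  x <- instance_features(train, manifest)
  norm <- fit_normalization(x)
  xn <- apply_normalization(norm, x)
  fraction <- config$features$subsample_fraction

  y1 <- factor(train$intensity, levels = intensity_levels())
  if (isTRUE(config$cascade$layer1_vent_only)) {
    subset1 <- .vent_feature_idx(manifest)
    learner1 <- base_learner_factory(spec, seed = node_seed(seed, 1L))
    layer1 <- list(model = learner1$fit(xn[, subset1, drop = FALSE], y1),
                   subset = subset1, learner = learner1)
  } else {
    layer1 <- .fit_node(xn, y1, spec, fraction, node_seed(seed, 1L))
  }

  present <- intersect(intensity_levels(), unique(train$intensity))
  layer2 <- lapply(present, function(int) {
    rows <- train$intensity == int
    y2 <- factor(train$activity[rows], levels = activities_of(int))
    .fit_node(xn[rows, , drop = FALSE], y2, spec, fraction,
              node_seed(seed, 1L + match(int, intensity_levels())))
  })
  names(layer2) <- present

  structure(
    list(layer1 = layer1, layer2 = layer2, normalization = norm,
         manifest = manifest, spec = spec, config = config, seed = seed),
    class = "ccm_model"
  )
}

#' @export
print.ccm_model <- function(x, ...) {
  cat(sprintf("<ccm_model> %s cascade: intensity layer + %d activity layer(s) [%s]\n",
              x$spec$kind, length(x$layer2),
              paste(names(x$layer2), collapse = ", ")))
  invisible(x)
}

.predict_matrix <- function(model, x) {
  if (is.data.frame(x)) x <- instance_features(x, model$manifest)
  x <- rbind(as.matrix(x))
  if (ncol(x) != length(model$manifest$names)) {
    stop(sprintf("expected %d features, got %d",
                 length(model$manifest$names), ncol(x)))
  }
  apply_normalization(model$normalization, x)
}

#' Predict intensity and activity with a fitted cascade
#'
#' @param model A `ccm_model`.
#' @param x Raw (unnormalised) feature matrix, single named feature vector,
#'   or a feature table containing the manifest columns.
#' @return data.frame with character columns `intensity` and `activity`,
#'   one row per input instance; every row satisfies
#'   `intensity_of(activity) == intensity`.
#' @export
predict_ccm <- function(model, x) {
  stopifnot(inherits(model, "ccm_model"))
  xn <- .predict_matrix(model, x)
  l1 <- model$layer1
  intensity <- as.character(
    l1$learner$predict(l1$model, xn[, l1$subset, drop = FALSE]))
  activity <- character(nrow(xn))
  for (int in unique(intensity)) {
    node <- model$layer2[[int]]
    if (is.null(node)) {
      stop("layer 1 predicted an intensity absent from training: ", int)
    }
    rows <- intensity == int
    activity[rows] <- as.character(
      node$learner$predict(node$model, xn[rows, node$subset, drop = FALSE]))
  }
  data.frame(intensity = intensity, activity = activity,
             stringsAsFactors = FALSE)
}

#' Train the flat (non-cascade) baseline
#'
#' A single multiclass classifier over all ten activity types, with the same
#' normalisation and feature-subsampling protocol as the cascade.
#'
#' @inheritParams train_ccm
#' @return A fitted `flat_model`.
#' @export
train_flat <- function(train, spec = NULL, config = ccm_config(), seed = 1L) {
  .check_train_table(train)
  if (is.null(spec)) spec <- learner_spec_from_config(config)
  manifest <- config_manifest(config)
  x <- instance_features(train, manifest)
  norm <- fit_normalization(x)
  xn <- apply_normalization(norm, x)
  y <- factor(train$activity, levels = activity_levels())
  node <- .fit_node(xn, y, spec, config$features$subsample_fraction,
                    node_seed(seed, 6L))
  structure(
    list(node = node, normalization = norm, manifest = manifest,
         spec = spec, config = config, seed = seed),
    class = "flat_model"
  )
}

#' Predict activity with the flat baseline
#'
#' @param model A `flat_model`.
#' @param x As in [predict_ccm()].
#' @return Character vector of activity codes.
#' @export
predict_flat <- function(model, x) {
  stopifnot(inherits(model, "flat_model"))
  xn <- .predict_matrix(model, x)
  node <- model$node
  as.character(node$learner$predict(node$model,
                                    xn[, node$subset, drop = FALSE]))
}
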