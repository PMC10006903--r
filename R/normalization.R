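#' Fit per-feature min-max normalisation on training data
#'
#' Learns, per feature, the training minimum and maximum. The fitted
#' transform maps a value `x` to `(x - min) / (max - min)`; training values
#' land exactly in `[0, 1]`, and unseen values are clipped to `[0, 1]`. A
#' feature that is constant on the training set maps to 0 (with a warning
#' when the state is fitted).
#'
#' @param train Numeric matrix of raw feature vectors (rows = instances).
#' @return A `normalization_state` list with `min` and `max` vectors.
#' @export
fit_normalization <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 1) stop("training set is empty")
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  if (any(hi == lo)) {
    warning("constant training feature(s) map to 0: ",
            paste(colnames(train)[hi == lo], collapse = ", "))
  }
  structure(list(min = lo, max = hi), class = "normalization_state")
}

#' Apply a fitted min-max normalisation
#'
#' @param state A `normalization_state` from [fit_normalization()].
#' @param x Numeric matrix (or single named vector) of raw features with the
#'   same columns the state was fitted on.
#' @return Matrix of the same shape with all values in `[0, 1]`.
#' @export
apply_normalization <- function(state, x) {
  stopifnot(inherits(state, "normalization_state"))
  single <- is.null(dim(x))
  x <- rbind(x)
  span <- state$max - state$min
  out <- sweep(x, 2, state$min, `-`)
  out <- sweep(out, 2, ifelse(span == 0, 1, span), `/`)
  out[, span == 0] <- 0
  out <- pmin(pmax(out, 0), 1)
  if (single) out[1, ] else out
}

#' Random feature subset for base-classifier diversity
#'
#' Draws `round(fraction * n_features)` distinct feature indices uniformly
#' without replacement. Each cascade node (and each cross-validation fold)
#' draws its own subset from its own seed, which decorrelates the base
#' classifiers.
#'
#' @param n_features Total number of features (default 64).
#' @param fraction Fraction to keep, in `(0, 1]`; default 0.7 (45 of 64).
#' @param seed Integer seed.
#' @return Sorted integer vector of feature indices.
#' @export
subsample_features <- function(n_features = 64L, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- max(1L, round(fraction * n_features))
  if (k >= n_features) return(seq_len(n_features))
  withr::with_seed(as.integer(seed), sort(sample.int(n_features, k)))
}
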