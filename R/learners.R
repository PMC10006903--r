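# Pluggable base learners: Random Forest, an SMO-style SVM, and k-NN.
#
# Each learner is wrapped behind a uniform fit/predict closure pair so the
# cascade and the flat baseline are agnostic to the algorithm. Hyperparameter
# defaults approximate the common defaults of standard toolkits: RF with 100
# trees, k-NN with k = 1, SVM with a degree-1 polynomial kernel and C = 1
# using one-vs-one multiclass voting. Training sets whose labels collapse to
# a single class yield a constant classifier (needed for degenerate cascade
# nodes).

#' Base-learner specification
#'
#' @param method One of `"RF"`, `"SMO"`, `"KNN"`.
#' @param ... Hyperparameter overrides: `ntree` (RF, default 100), `k` (KNN,
#'   default 1), `cost` and `degree` (SMO, defaults 1 and 1).
#' @return A `base_learner_spec` list with elements `kind` and
#'   `hyperparameters`.
#' @export
#' @examples
#' base_learner_spec("RF", ntree = 50)
base_learner_spec <- function(method = c("RF", "SMO", "KNN"), ...) {
  kind <- match.arg(method)
  hp <- list(...)
  defaults <- switch(kind,
    RF = list(ntree = 100L),
    KNN = list(k = 1L),
    SMO = list(cost = 1, degree = 1L)
  )
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown ", kind, " hyperparameter(s): ",
         paste(unknown, collapse = ", "))
  }
  hp <- utils::modifyList(defaults, hp)
  if (kind == "RF" && hp$ntree < 1) stop("ntree must be >= 1")
  if (kind == "KNN" && hp$k < 1) stop("k must be >= 1")
  if (kind == "SMO" && hp$cost <= 0) stop("cost must be > 0")
  structure(list(kind = kind, hyperparameters = hp),
            class = "base_learner_spec")
}

# Exact k-NN with deterministic tie-breaks: neighbours are ordered by
# distance then training index; vote ties go to the lowest label index.
.knn_fit <- function(x, y, k) {
  list(x = x, y = y, k = min(k, nrow(x)))
}

.knn_predict <- function(model, newx) {
  tr <- model$x
  d2 <- outer(rowSums(newx^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(newx)), rowSums(tr^2)) - 2 * newx %*% t(tr)
  lev <- levels(model$y)
  idx <- apply(d2, 1, function(row) {
    nb <- order(row)[seq_len(model$k)]
    votes <- tabulate(as.integer(model$y[nb]), nbins = length(lev))
    which.max(votes)  # first max = lowest label index
  })
  factor(lev[idx], levels = lev)
}

#' Construct a trainable classifier from a specification
#'
#' @param spec A [base_learner_spec()].
#' @param seed Integer seed consumed by stochastic learners (RF); the SVM
#'   and k-NN paths are deterministic.
#' @return List with `fit(x, y)` (numeric matrix, factor) returning a fitted
#'   model, and `predict(model, x)` returning a factor with `levels(y)`.
#' @export
base_learner_factory <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "base_learner_spec"))
  hp <- spec$hyperparameters
  seed <- as.integer(seed)

  fit_inner <- switch(spec$kind,
    RF = function(x, y) {
      withr::with_seed(seed, randomForest::randomForest(
        x = x, y = y, ntree = hp$ntree))
    },
    SMO = function(x, y) {
      e1071::svm(x = x, y = y, kernel = "polynomial", degree = hp$degree,
                 coef0 = 0, cost = hp$cost, scale = FALSE)
    },
    KNN = function(x, y) .knn_fit(x, y, hp$k)
  )
  predict_inner <- switch(spec$kind,
    RF = function(model, x) stats::predict(model, x),
    SMO = function(model, x) stats::predict(model, x),
    KNN = .knn_predict
  )

  fit <- function(x, y) {
    x <- as.matrix(x)
    y <- droplevels(as.factor(y))
    stopifnot(nrow(x) == length(y))
    if (nlevels(y) == 1L) {
      return(structure(list(label = levels(y)), class = "constant_classifier"))
    }
    model <- fit_inner(x, y)
    attr(model, "label_levels") <- levels(y)
    model
  }
  predict_ <- function(model, x) {
    x <- rbind(as.matrix(x))
    if (inherits(model, "constant_classifier")) {
      return(factor(rep(model$label, nrow(x)), levels = model$label))
    }
    pred <- predict_inner(model, x)
    factor(as.character(pred), levels = attr(model, "label_levels"))
  }
  list(fit = fit, predict = predict_, spec = spec, seed = seed)
}
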