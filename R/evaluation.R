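# Leave-one-subject-out evaluation and macro-averaged metrics.

#' Leave-one-subject-out folds
#'
#' Selects `n_subjects_eval` subjects (seeded, without replacement) and
#' builds one fold per selected subject: the fold's test set is exactly that
#' subject's instances and its training set is all other subjects'
#' instances, so no subject contributes to both sides.
#'
#' @param instances Feature table with a `subject_id` column.
#' @param n_subjects_eval Number of held-out subjects; `NULL` (default)
#'   iterates every subject.
#' @param seed Integer seed for the subject selection.
#' @return List of folds: each a list with `subject`, `train` and `test`
#'   (integer row indices into `instances`).
#' @export
loso_folds <- function(instances, n_subjects_eval = NULL, seed = 1L) {
  subjects <- unique(instances$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects for LOSO")
  if (is.null(n_subjects_eval)) n_subjects_eval <- length(subjects)
  if (n_subjects_eval < 1) stop("n_subjects_eval must be >= 1")
  if (n_subjects_eval > length(subjects)) {
    stop("n_subjects_eval exceeds the number of subjects")
  }
  chosen <- withr::with_seed(as.integer(seed),
                             sample(subjects, n_subjects_eval))
  lapply(chosen, function(s) {
    list(subject = s,
         train = which(instances$subject_id != s),
         test = which(instances$subject_id == s))
  })
}

#' Confusion matrix over an ordered label set
#'
#' @param true,predicted Vectors of labels, equal length.
#' @param labels Ordered label set; every observed label must belong to it.
#'   Zero-count rows/columns are kept so the matrix is always square over
#'   the declared order.
#' @return Integer matrix (rows = true, columns = predicted) of class
#'   `confusion_matrix`.
#' @export
confusion <- function(true, predicted, labels) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (length(true) != length(predicted)) stop("label vectors differ in length")
  outside <- setdiff(unique(c(true, predicted)), labels)
  if (length(outside) > 0) {
    stop("label(s) outside the declared order: ",
         paste(outside, collapse = ", "))
  }
  m <- table(factor(true, levels = labels), factor(predicted, levels = labels))
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Macro-averaged metrics from a confusion matrix
#'
#' Overall accuracy is `trace / total`. The other four metrics are computed
#' one-vs-rest per class c — `TP = m[c,c]`, `FP = colsum - TP`,
#' `FN = rowsum - TP`, `TN = total - TP - FP - FN` — giving sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and
#' F1 `2*sens*prec/(sens+prec)`, then macro-averaged as the unweighted mean
#' over classes (macro-F1 is the mean of per-class F1 values, not the F1 of
#' the macro precision/recall). Classes with zero true and zero predicted
#' instances are excluded from the macro averages with a warning.
#'
#' @param m A square confusion matrix (rows = true, columns = predicted).
#' @return A `metrics_report` list: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, the `per_class` data.frame and the
#'   instance count `n`.
#' @export
metrics_from_confusion <- function(m) {
  m <- unclass(as.matrix(m))
  stopifnot(nrow(m) == ncol(m))
  total <- sum(m)
  if (total <= 0) stop("confusion matrix is empty")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  support <- rowSums(m) + colSums(m)
  keep <- support > 0
  if (!all(keep)) {
    warning("class(es) with no true or predicted instances excluded ",
            "from macro averages: ", paste(labels[!keep], collapse = ", "))
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- tp / (tp + fp)
  f1 <- 2 * sens * prec / (sens + prec)
  # a class never predicted has precision 0/0; score it 0 rather than NA
  prec[keep & !is.finite(prec)] <- 0
  sens[keep & !is.finite(sens)] <- 0
  f1[keep & !is.finite(f1)] <- 0
  per_class <- data.frame(
    class = labels, tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
    row.names = NULL, stringsAsFactors = FALSE
  )[keep, ]
  structure(
    list(accuracy = sum(tp) / total,
         sensitivity = mean(per_class$sensitivity),
         specificity = mean(per_class$specificity),
         precision = mean(per_class$precision),
         f1 = mean(per_class$f1),
         per_class = per_class, n = total),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<metrics_report> n = %d | accuracy %.*f | sensitivity %.*f | specificity %.*f | precision %.*f | F1 %.*f\n",
    x$n, digits, x$accuracy, digits, x$sensitivity, digits, x$specificity,
    digits, x$precision, digits, x$f1))
  invisible(x)
}

#' Run the full LOSO evaluation pipeline
#'
#' Segments and featurises the data (if given as recordings), then for each
#' leave-one-subject-out fold fits normalisation, feature subsets and the
#' classifier on the training subjects only, predicts the held-out subject,
#' and pools the test predictions across folds into a single confusion
#' matrix. Per-fold accuracies (mean and sd) are reported alongside the
#' pooled metrics; in cascade mode the intensity layer gets its own pooled
#' confusion matrix and report.
#'
#' @param data Either a list of `sensor_recording` objects or a
#'   ready-made feature table from [features_table()].
#' @param spec A [base_learner_spec()]; default from `config`.
#' @param mode `"ccm"` (cascade) or `"flat"` (single ten-way classifier).
#' @param config A [ccm_config()].
#' @param seed Integer seed (fold selection and per-fold/node seeds derive
#'   from it).
#' @return A `ccm_evaluation` list: `mode`, `folds` (per-fold results),
#'   `pooled_confusion`, `metrics`, `fold_accuracies`, `mean_accuracy`,
#'   `sd_accuracy`, and for ccm mode `layer1_confusion` / `layer1_metrics`.
#' @export
evaluate_pipeline <- function(data, spec = NULL, mode = c("ccm", "flat"),
                              config = ccm_config(), seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(spec)) spec <- learner_spec_from_config(config)
  tab <- if (is.data.frame(data)) data else {
    features_table(segment_all(data, config$features$window_seconds),
                   config_manifest(config))
  }
  folds <- loso_folds(tab, config$evaluation$n_subjects_eval, seed)
  if (mode == "ccm" && length(unique(tab$intensity)) < 2) {
    # degenerate but legal: the cascade collapses to its single layer-2 node
    message("single intensity category: cascade degenerates to one node")
  }

  fold_results <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    train <- tab[f$train, , drop = FALSE]
    test <- tab[f$test, , drop = FALSE]
    fold_seed <- node_seed(seed, 0L, fold = i)
    res <- tryCatch({
      if (mode == "ccm") {
        model <- train_ccm(train, spec, config, seed = fold_seed)
        pred <- predict_ccm(model, test)
      } else {
        model <- train_flat(train, spec, config, seed = fold_seed)
        pred <- data.frame(intensity = NA_character_,
                           activity = predict_flat(model, test),
                           stringsAsFactors = FALSE)
      }
      list(model_norm = model$normalization, pred = pred)
    }, error = function(e) {
      stop("fold ", i, " (held-out subject ", f$subject, "): ",
           conditionMessage(e))
    })
    fold_results[[i]] <- list(
      subject = f$subject,
      n_test = nrow(test),
      true_activity = test$activity,
      true_intensity = test$intensity,
      pred_activity = res$pred$activity,
      pred_intensity = res$pred$intensity,
      accuracy = mean(res$pred$activity == test$activity),
      normalization = res$model_norm
    )
  }

  true_act <- unlist(lapply(fold_results, `[[`, "true_activity"))
  pred_act <- unlist(lapply(fold_results, `[[`, "pred_activity"))
  pooled <- confusion(true_act, pred_act, activity_levels())
  metrics <- suppressWarnings(metrics_from_confusion(pooled))
  fold_acc <- vapply(fold_results, `[[`, numeric(1), "accuracy")

  out <- list(
    mode = mode, spec = spec, seed = seed, folds = fold_results,
    pooled_confusion = pooled, metrics = metrics,
    fold_accuracies = fold_acc, mean_accuracy = mean(fold_acc),
    sd_accuracy = stats::sd(fold_acc)
  )
  if (mode == "ccm") {
    true_int <- unlist(lapply(fold_results, `[[`, "true_intensity"))
    pred_int <- unlist(lapply(fold_results, `[[`, "pred_intensity"))
    out$layer1_confusion <- confusion(true_int, pred_int, intensity_levels())
    out$layer1_metrics <- suppressWarnings(
      metrics_from_confusion(out$layer1_confusion))
  }
  structure(out, class = "ccm_evaluation")
}

#' @export
print.ccm_evaluation <- function(x, ...) {
  cat(sprintf(
    "<ccm_evaluation> mode %s (%s), %d folds, pooled accuracy %.4f (per-fold %.4f +/- %.4f)\n",
    x$mode, x$spec$kind, length(x$folds), x$metrics$accuracy,
    x$mean_accuracy, x$sd_accuracy))
  if (!is.null(x$layer1_metrics)) {
    cat(sprintf("  intensity layer pooled accuracy %.4f\n",
                x$layer1_metrics$accuracy))
  }
  invisible(x)
}

#' Compare the cascade against the flat baseline over multiple seeds
#'
#' Runs [evaluate_pipeline()] in both modes for each seed on the same data
#' (features are computed once) and reports paired pooled accuracies, the
#' mean difference, and the structural check that the cascade's end-to-end
#' accuracy never exceeds its intensity-layer accuracy.
#'
#' @param data Recordings list or feature table, as in
#'   [evaluate_pipeline()].
#' @param spec A [base_learner_spec()]; default from `config`.
#' @param config A [ccm_config()].
#' @param seeds Integer vector of seeds (>= 1 seed).
#' @return A `ccm_comparison` list: `rows` (one data.frame row per
#'   (seed, mode)), `mean_ccm`, `mean_flat`, `mean_diff`,
#'   `layer1_bound_ok`.
#' @export
compare_modes <- function(data, spec = NULL, config = ccm_config(),
                          seeds = 1:10) {
  if (length(seeds) < 1) stop("need at least one seed")
  if (is.null(spec)) spec <- learner_spec_from_config(config)
  tab <- if (is.data.frame(data)) data else {
    features_table(segment_all(data, config$features$window_seconds),
                   config_manifest(config))
  }
  rows <- list()
  for (s in seeds) {
    ev_ccm <- evaluate_pipeline(tab, spec, "ccm", config, seed = s)
    ev_flat <- evaluate_pipeline(tab, spec, "flat", config, seed = s)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, mode = "ccm",
      accuracy = ev_ccm$metrics$accuracy,
      mean_fold_accuracy = ev_ccm$mean_accuracy,
      sd_fold_accuracy = ev_ccm$sd_accuracy,
      layer1_accuracy = ev_ccm$layer1_metrics$accuracy,
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, mode = "flat",
      accuracy = ev_flat$metrics$accuracy,
      mean_fold_accuracy = ev_flat$mean_accuracy,
      sd_fold_accuracy = ev_flat$sd_accuracy,
      layer1_accuracy = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  rows <- do.call(rbind, rows)
  ccm_rows <- rows[rows$mode == "ccm", ]
  flat_rows <- rows[rows$mode == "flat", ]
  structure(
    list(rows = rows,
         mean_ccm = mean(ccm_rows$accuracy),
         mean_flat = mean(flat_rows$accuracy),
         mean_layer1 = mean(ccm_rows$layer1_accuracy),
         mean_diff = mean(ccm_rows$accuracy) - mean(flat_rows$accuracy),
         layer1_bound_ok = all(ccm_rows$accuracy <=
                                 ccm_rows$layer1_accuracy + 1e-12)),
    class = "ccm_comparison"
  )
}

#' @export
print.ccm_comparison <- function(x, ...) {
  cat(sprintf(
    "<ccm_comparison> %d seed(s): mean accuracy cascade %.4f vs flat %.4f (diff %+.4f); intensity layer %.4f\n",
    length(unique(x$rows$seed)), x$mean_ccm, x$mean_flat, x$mean_diff,
    x$mean_layer1))
  invisible(x)
}
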