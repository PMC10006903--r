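test_that("LOSO folds isolate exactly one subject per fold", {
  tab <- noisy_table()
  folds <- loso_folds(tab, seed = 1)
  expect_length(folds, 4L)
  for (f in folds) {
    expect_equal(unique(tab$subject_id[f$test]), f$subject)
    expect_false(f$subject %in% tab$subject_id[f$train])
    expect_length(intersect(f$train, f$test), 0L)
    expect_equal(sort(c(f$train, f$test)), seq_len(nrow(tab)))
  }
  expect_setequal(vapply(folds, `[[`, character(1), "subject"),
                  unique(tab$subject_id))
  # seeded subject selection
  f2 <- loso_folds(tab, n_subjects_eval = 2, seed = 9)
  f3 <- loso_folds(tab, n_subjects_eval = 2, seed = 9)
  expect_identical(lapply(f2, `[[`, "subject"), lapply(f3, `[[`, "subject"))
  expect_error(loso_folds(tab, n_subjects_eval = 0), ">= 1")
  expect_error(loso_folds(tab, n_subjects_eval = 10), "exceeds")
  expect_error(loso_folds(tab[tab$subject_id == "S001", ]), "at least 2")
})

test_that("confusion matrices count correctly over the declared label order", {
  lab <- c("a", "b", "c")
  m <- confusion(c("a", "b", "c"), c("a", "b", "c"), lab)
  expect_equal(unclass(m), diag(3L), ignore_attr = TRUE)
  m1 <- confusion("b", "c", lab)
  expect_equal(sum(m1), 1L)
  expect_equal(m1["b", "c"], 1L)
  expect_error(confusion("a", "z", lab), "outside")
  expect_error(confusion(c("a", "b"), "a", lab), "length")
})

test_that("expanding a reference count matrix to a label stream and
           recounting reproduces it exactly", {
  ref <- ccm_reference_confusions()$KNN
  lv <- intensity_levels()
  true <- rep(rep(lv, times = rowSums(ref)), times = 1)
  pred <- unlist(lapply(lv, function(r) rep(lv, times = ref[r, ])))
  m <- confusion(true, pred, lv)
  expect_equal(unclass(m), unclass(ref), ignore_attr = TRUE)
})

test_that("metrics are 1.0 on a perfect diagonal matrix and handle
           zero-support classes", {
  m <- diag(10L, 4)
  rownames(m) <- colnames(m) <- intensity_levels()
  rep_ <- metrics_from_confusion(m)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$specificity, 1)
  expect_equal(rep_$precision, 1)
  expect_equal(rep_$f1, 1)
  expect_equal(rep_$n, 40)

  m2 <- m
  m2[4, ] <- 0L                          # vigorous never occurs nor predicted
  expect_warning(r2 <- metrics_from_confusion(m2), "excluded")
  expect_equal(nrow(r2$per_class), 3L)
  expect_equal(r2$accuracy, 1)
})

test_that("the pipeline pools fold predictions consistently and without
           leakage", {
  tab <- noisy_table()
  cfg <- ccm_config()
  ev <- evaluate_pipeline(tab, base_learner_spec("KNN"), "ccm", cfg, seed = 2)
  # pooling: matrix total equals the sum of fold test sizes
  expect_equal(sum(ev$pooled_confusion),
               sum(vapply(ev$folds, `[[`, integer(1), "n_test")))
  # pooled accuracy equals the instance-weighted mean of fold accuracies
  w <- vapply(ev$folds, `[[`, integer(1), "n_test")
  expect_equal(ev$metrics$accuracy,
               sum(ev$fold_accuracies * w) / sum(w))
  # cascade accuracy never exceeds the intensity-layer accuracy
  expect_lte(ev$metrics$accuracy, ev$layer1_metrics$accuracy + 1e-12)
  # no leakage: each fold's normalisation state is exactly the min/max of
  # that fold's training rows
  x <- instance_features(tab)
  for (i in seq_along(ev$folds)) {
    f <- ev$folds[[i]]
    train_rows <- tab$subject_id != f$subject
    expect_equal(ev$folds[[i]]$normalization$min,
                 apply(x[train_rows, ], 2, min))
    expect_equal(ev$folds[[i]]$normalization$max,
                 apply(x[train_rows, ], 2, max))
  }
})

test_that("noise-free evaluation is perfect with zero fold-accuracy spread", {
  tab <- noisefree_table()
  ev <- evaluate_pipeline(tab, base_learner_spec("RF"), "ccm",
                          ccm_config(), seed = 5)
  expect_equal(ev$metrics$accuracy, 1)
  expect_equal(ev$sd_accuracy, 0)
})

test_that("flat and cascade evaluations coincide on single-intensity data
           under shared seeds and full feature sets", {
  tab <- moderate_table()
  cfg <- ccm_config(features = list(subsample_fraction = 1.0))
  # messages/warnings expected: degenerate cascade, constant breathing bin
  suppressMessages(suppressWarnings({
    ev_c <- evaluate_pipeline(tab, base_learner_spec("KNN"), "ccm", cfg, seed = 3)
  }))
  ev_f <- suppressWarnings(
    evaluate_pipeline(tab, base_learner_spec("KNN"), "flat", cfg, seed = 3))
  expect_equal(ev_c$metrics$accuracy, ev_f$metrics$accuracy)
  expect_equal(unclass(ev_c$pooled_confusion), unclass(ev_f$pooled_confusion))
})

test_that("mode comparison reports one row per (mode, seed) and respects the
           intensity-layer bound", {
  tab <- noisy_table()
  cmp <- compare_modes(tab, base_learner_spec("KNN"), ccm_config(), seeds = c(2, 4))
  expect_equal(nrow(cmp$rows), 4L)
  expect_setequal(cmp$rows$mode, c("ccm", "flat"))
  expect_true(cmp$layer1_bound_ok)
  ccm_rows <- cmp$rows[cmp$rows$mode == "ccm", ]
  expect_true(all(ccm_rows$accuracy <= ccm_rows$layer1_accuracy + 1e-12))
  expect_equal(cmp$mean_diff, cmp$mean_ccm - cmp$mean_flat)
})

test_that("the bundled reference metrics are reproduced cell by cell and
           tampering is detected", {
  v <- ccm_verify_reference()
  expect_equal(nrow(v), 15L)
  expect_true(all(v$match))
  bad <- ccm_reference_confusions()
  bad$RF[1, 2] <- bad$RF[1, 2] + 25L
  v2 <- ccm_verify_reference(confusions = bad)
  expect_gt(sum(!v2$match), 0)
})
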