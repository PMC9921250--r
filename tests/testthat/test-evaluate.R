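test_that("confusion counts follow the four definitions", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0)
  expect_error_class(confusion(c(1, 2), c(0, 1)), "label_error")
  expect_error_class(confusion(c(1, 0), c(1)), "label_error")
  # exhaustive: all 16 (y_true, y_pred) patterns of length 2
  for (a1 in 0:1) for (a2 in 0:1) for (b1 in 0:1) for (b2 in 0:1) {
    yt <- c(a1, a2); yp <- c(b1, b2)
    cc <- confusion(yt, yp)
    brute <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    for (i in 1:2) {
      k <- if (yt[i] == 1 && yp[i] == 1) "tp" else if (yt[i] == 0 && yp[i] == 1) "fp"
           else if (yt[i] == 1 && yp[i] == 0) "fn" else "tn"
      brute[k] <- brute[k] + 1
    }
    expect_equal(unlist(unclass(cc)), brute)
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 2)   # N identity
  }
})

test_that("metrics reproduce the published formulas", {
  m <- metrics(confusion(rep(c(1, 1, 0, 0), c(50, 5, 40, 5)),
                         rep(c(1, 0, 0, 1), c(50, 5, 40, 5))))
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$sensitivity, 50 / 55)
  expect_equal(m$specificity, 40 / 45)
  expect_equal(m$precision, 50 / 55)
  expect_length(m$undefined, 0)
  # degenerate: no positives predicted or present
  d <- metrics(structure(list(tp = 0L, fp = 0L, fn = 0L, tn = 10L),
                         class = "confusion_counts"))
  expect_equal(d$accuracy, 1.0)
  expect_true(is.na(d$precision))
  expect_setequal(d$undefined, c("precision", "sensitivity", "f1"))
})

test_that("label swap is an involution on the metrics", {
  set.seed(40)
  yt <- rbinom(60, 1, 0.5); yp <- rbinom(60, 1, 0.5)
  m1 <- metrics(confusion(yt, yp))
  m2 <- metrics(confusion(1 - yt, 1 - yp))
  expect_equal(m1$sensitivity, m2$specificity)
  expect_equal(m1$specificity, m2$sensitivity)
  expect_equal(m1$counts$tp, m2$counts$tn)
  expect_equal(m1$counts$fp, m2$counts$fn)
})

test_that("stratified folds partition rows and preserve class balance", {
  y <- rep(0:1, 50)
  f <- stratified_kfold(y, 10, seed = 3)
  expect_equal(as.vector(table(f)), rep(10, 10))
  for (k in 1:10) expect_equal(sum(y[f == k]), 5)
  expect_identical(f, stratified_kfold(y, 10, seed = 3))   # determinism
  y4 <- c(0, 0, 1, 1)
  f4 <- stratified_kfold(y4, 2, seed = 1)
  expect_equal(as.vector(table(f4)), c(2, 2))
  for (k in 1:2) expect_equal(sum(y4[f4 == k]), 1)
  expect_error_class(stratified_kfold(c(0, 0, 0, 1), 2, seed = 1),
                     "stratification_error")
})

test_that("cross_validate respects fold bounds and determinism", {
  b <- planted_signal_benchmark(2, 2, 120, seed = 44)
  cv <- cross_validate(b$dataset, fast_base_cfgs("lr"), "single:lr",
                       k = 4, seed = 7)
  accs <- vapply(cv$per_fold, `[[`, numeric(1), "accuracy")
  expect_gte(cv$mean_metrics[["accuracy"]], min(accs))
  expect_lte(cv$mean_metrics[["accuracy"]], max(accs))
  cv2 <- cross_validate(b$dataset, fast_base_cfgs("lr"), "single:lr",
                        k = 4, seed = 7)
  expect_identical(cv$mean_metrics, cv2$mean_metrics)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
})

test_that("compare_combiners equals per-combiner cross_validate", {
  b <- planted_signal_benchmark(2, 2, 100, seed = 50)
  cfgs <- fast_base_cfgs(c("lr", "rf"), seed = 1)
  shared <- compare_combiners(b$dataset, cfgs,
                              combiners = c("majority", "single:lr"),
                              k = 4, seed = 9, oof_folds = 3)
  solo <- cross_validate(b$dataset, cfgs, "majority", k = 4, seed = 9,
                         oof_folds = 3)
  expect_equal(shared$majority$mean_metrics, solo$mean_metrics)
  solo_lr <- cross_validate(b$dataset, cfgs, "single:lr", k = 4, seed = 9)
  expect_equal(shared$`single:lr`$mean_metrics, solo_lr$mean_metrics)
})

test_that("comparison reports have the published shapes", {
  ds <- separable_dataset(n = 60, gap = 5, seed = 13)
  cfgs <- fast_base_cfgs(c("lr", "rf"), seed = 1)
  t4 <- compare_frameworks(ds, cfgs, mode = "table4", k = 3, seed = 2,
                           preprocess = NULL, oof_folds = 3)
  expect_equal(nrow(t4), 4)
  expect_identical(t4$model[1:3], c("proposed_framework",
                                    "traditional_voting",
                                    "classical_stacking"))
  expect_true(startsWith(t4$model[4], "best_single:"))
  # degenerate separable data: every framework is perfect
  expect_true(all(t4$accuracy == 100))

  t3 <- compare_frameworks(ds, cfgs, mode = "table3", k = 3, seed = 2,
                           preprocess = preprocess_config(contamination = 0,
                                                          seed = 2))
  expect_equal(nrow(t3), 4)   # 2 models x 2 pipeline conditions
  expect_setequal(unique(t3$condition),
                  c("with_preprocessing", "without_preprocessing"))
})

test_that("table3 mode covers all six models twice", {
  # shape check only: six fast configs on a tiny separable set
  ds <- separable_dataset(n = 50, gap = 6, seed = 21)
  cfgs <- fast_base_cfgs(c("lr", "svm", "xgb", "rf", "dnn", "cnn"), seed = 1)
  t3 <- compare_frameworks(ds, cfgs, mode = "table3", k = 2, seed = 3,
                           preprocess = NULL)
  expect_equal(nrow(t3), 12)
  expect_equal(sum(t3$condition == "with_preprocessing"), 6)
})
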