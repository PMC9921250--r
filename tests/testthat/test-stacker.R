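test_that("meta-feature layout is (class_i, p_i) blocks in model order", {
  set.seed(1)
  cls <- matrix(rbinom(600, 1, 0.5), 100, 6)
  prb <- matrix(runif(600), 100, 6)
  out <- fake_outputs(cls, prb)
  mf <- build_meta_features(out, names(out))
  expect_equal(dim(mf), c(100, 12))
  expect_identical(colnames(mf)[1:4], c("class_m1", "p_m1", "class_m2", "p_m2"))
  expect_true(all(mf[, seq(1, 11, 2)] %in% c(0, 1)))
  expect_true(all(mf[, seq(2, 12, 2)] >= 0 & mf[, seq(2, 12, 2)] <= 1))

  one <- fake_outputs(matrix(1, 1, 1), matrix(0.9, 1, 1))
  expect_equal(unname(build_meta_features(one, "m1")[1, ]), c(1, 0.9))

  # permuting model_order permutes the column blocks identically
  perm <- c("m3", "m1", "m6", "m2", "m5", "m4")
  mfp <- build_meta_features(out, perm)
  expect_identical(mfp[, "p_m3"], mf[, "p_m3"])
  expect_identical(colnames(mfp)[1:2], c("class_m3", "p_m3"))

  expect_error_class(build_meta_features(out[1:5], names(out)),
                     "ensemble_mismatch_error")
  # classical variant keeps the class columns only
  expect_equal(ncol(build_meta_features(out, names(out), include = "class")), 6)
})

test_that("a perfect oracle base gives perfect stacked training accuracy", {
  ds <- separable_dataset(n = 60, gap = 6, seed = 5)
  sm <- fit_stacked(ds, fast_base_cfgs("lr"), oof_folds = 5, seed = 1)
  pr <- predict_stacked(sm, ds)
  expect_equal(mean(pr$class == dataset_labels(ds)), 1.0)
  expect_identical(pr$class, as.integer(pr$prob >= 0.5))
})

test_that("constant base outputs yield the majority class", {
  set.seed(9)
  y <- rep(c(0, 1), c(45, 15))             # majority class 0
  ds <- toy_dataset(matrix(rnorm(120), 60, 2), y)
  # rf stub: constant features force constant predictions
  flat <- toy_dataset(matrix(0, 60, 2), y)
  sm <- fit_stacked(flat, fast_base_cfgs(c("lr", "rf")), oof_folds = 3, seed = 2)
  pr <- predict_stacked(sm, flat)
  expect_true(all(pr$class == 0))
})

test_that("out-of-fold meta matrix equals an independent manual fold loop", {
  set.seed(22)
  b <- planted_signal_benchmark(2, 2, 200, seed = 22)
  ds <- b$dataset
  cfgs <- fast_base_cfgs(c("lr", "rf"), seed = 3)
  oof <- clinstack:::.oof_outputs(ds, cfgs, 5, seed = 11)
  # independent reconstruction: same stratified folds, manual training loop
  y <- dataset_labels(ds)
  folds <- stratified_kfold(y, 5, seed = 11)
  expect_identical(folds, oof$folds)
  manual <- lapply(cfgs, function(cfg) list(class = integer(200),
                                            prob = numeric(200)))
  for (f in 1:5) {
    tr <- subset_rows(ds, folds != f)
    te <- subset_rows(ds, folds == f)
    for (m in names(cfgs)) {
      pr <- predict_base(train_base(tr, cfgs[[m]]), te)
      manual[[m]]$class[folds == f] <- pr$class
      manual[[m]]$prob[folds == f] <- pr$prob
    }
  }
  expect_identical(oof$outputs, manual)
  # out-of-fold discipline is recorded in the protocol
  sm <- fit_stacked(ds, cfgs, oof_folds = 5, seed = 11)
  expect_equal(sm$protocol$oof_folds, 5)
  expect_identical(sm$protocol$fold_assignment, folds)
  expect_false(sm$protocol$in_sample)
})

test_that("predict_stacked evaluates the meta logistic in closed form", {
  ds <- separable_dataset(n = 30, gap = 6, seed = 8)
  sm <- fit_stacked(ds, fast_base_cfgs("lr"), oof_folds = 3, seed = 1)
  # null meta model -> probability 0.5 everywhere
  sm0 <- sm
  sm0$meta <- list(intercept = 0, beta = c(0, 0))
  expect_equal(predict_stacked(sm0, ds)$prob, rep(0.5, 30))
  # hand-set coefficients -> closed-form sigmoid of (w_c*class + w_p*p + b)
  smh <- sm
  smh$meta <- list(intercept = -0.5, beta = c(0.8, 1.5))
  base_pr <- predict_base(sm$bases$lr, ds)
  eta <- -0.5 + 0.8 * base_pr$class + 1.5 * base_pr$prob
  expect_equal(predict_stacked(smh, ds)$prob, 1 / (1 + exp(-eta)),
               tolerance = 1e-12)
})

test_that("majority vote agrees with exhaustive counting (M = 3 and ties)", {
  out <- fake_outputs(matrix(c(1, 1, 0), 1), matrix(c(0.9, 0.8, 0.1), 1))
  expect_equal(majority_vote(out), 1L)
  # M = 6 tie broken by mean positive probability
  tie_hi <- fake_outputs(matrix(c(1, 1, 1, 0, 0, 0), 1),
                         matrix(rep(0.7, 6), 1))
  expect_equal(majority_vote(tie_hi), 1L)
  tie_lo <- fake_outputs(matrix(c(1, 1, 1, 0, 0, 0), 1),
                         matrix(rep(0.3, 6), 1))
  expect_equal(majority_vote(tie_lo), 0L)
  expect_error_class(majority_vote(list()), "argument_error")
})

test_that("classical stacking is the class-column restriction of proposed", {
  set.seed(33)
  b <- planted_signal_benchmark(2, 1, 120, seed = 33)
  cfgs <- fast_base_cfgs(c("lr", "rf"), seed = 2)
  prop <- fit_stacked(b$dataset, cfgs, oof_folds = 3, seed = 4)
  clas <- fit_classical_stack(b$dataset, cfgs, oof_folds = 3, seed = 4)
  expect_equal(prop$meta_width, 4)
  expect_equal(clas$meta_width, 2)
  out <- lapply(prop$bases, predict_base, rows = b$dataset)
  both <- build_meta_features(out, prop$model_order, "both")
  cls <- build_meta_features(out, clas$model_order, "class")
  expect_identical(both[, colnames(cls)], cls)
  # width mismatch errors at predict time
  broken <- prop
  broken$meta_width <- 99
  expect_error_class(predict_stacked(broken, b$dataset),
                     "ensemble_mismatch_error")
})

test_that("with M = 1 stacking tracks the base model on separable data", {
  ds <- separable_dataset(n = 100, gap = 4, seed = 12)
  cfgs <- fast_base_cfgs("lr")
  res <- compare_combiners(ds, cfgs, combiners = c("proposed", "single:lr"),
                           k = 5, seed = 2, oof_folds = 3)
  expect_gte(res$proposed$mean_metrics[["accuracy"]],
             res$`single:lr`$mean_metrics[["accuracy"]] - 0.02)
})
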