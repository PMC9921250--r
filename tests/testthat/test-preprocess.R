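test_that("duplicate removal keeps first occurrences in order", {
  ds <- toy_dataset(cbind(c(1, 2, 1), c(5, 6, 5)), c(1, 0, 1))
  out <- remove_duplicates(ds)
  expect_equal(out$count, 1)
  expect_equal(n_rows(out$dataset), 2)
  expect_equal(out$dataset$data$f1, c(1, 2))

  ds2 <- toy_dataset(cbind(1:4, 5:8), c(1, 0, 1, 0))
  out2 <- remove_duplicates(ds2)
  expect_equal(out2$count, 0)
  expect_equal(out2$dataset$data, ds2$data)

  # 10 rows with 3 copies of one tuple -> 8 rows; verify against brute force
  x <- cbind(c(9, 1:7, 9, 9), c(3, 11:17, 3, 3))
  y <- c(1, rep(0, 7), 1, 1)
  out3 <- remove_duplicates(toy_dataset(x, y))
  expect_equal(n_rows(out3$dataset), 8)
  expect_equal(out3$count, 2)
  brute <- sum(vapply(seq_along(y), function(i)
    any(vapply(seq_len(i - 1), function(j)
      all(x[i, ] == x[j, ]) && y[i] == y[j], logical(1))), logical(1)))
  expect_equal(out3$count, brute)
})

test_that("label-distribution imputation fills with the class mean", {
  x <- cbind(c(8, 12, NA, 100), c(1, 2, 3, 4))
  y <- c(0, 0, 0, 1)
  ds <- toy_dataset(x, y)
  out <- impute_nulls(ds, preprocess_config(impute_method = "label_distribution"))
  expect_equal(out$count, 1)
  expect_equal(out$dataset$data$f1[3], 10)      # mean of class-0 values 8, 12
})

test_that("knn imputation equals the brute-force neighbour oracle", {
  # hand-built 4-row table; cell (1, f1) missing
  x <- cbind(c(NA, 10, 20, 11), c(5, 5.1, 30, 4.9))
  y <- c(1, 1, 0, 1)
  ds <- toy_dataset(x, y)
  out <- impute_nulls(ds, preprocess_config(impute_method = "knn", knn_k = 2L))
  # exhaustive distances from row 1 on shared observed feature f2:
  d <- abs(x[2:4, 2] - x[1, 2])          # rows 2,3,4 -> 0.1, 25, 0.1
  nearest2 <- (2:4)[order(d)][1:2]       # rows 2 and 4
  expect_equal(out$dataset$data$f1[1], mean(x[nearest2, 1]))
  expect_equal(out$count, 1)
  # no-missing identity
  full <- toy_dataset(cbind(1:4, 5:8), c(1, 0, 1, 0))
  expect_equal(impute_nulls(full, preprocess_config())$count, 0)
})

test_that("fully missing columns are unimputable", {
  ds <- toy_dataset(cbind(c(NA, NA, NA), 1:3), c(1, 0, 1))
  expect_error_class(impute_nulls(ds, preprocess_config()),
                     "unimputable_column_error")
})

test_that("after imputation a full scan finds zero missing cells", {
  spec <- synthetic_spec(toy_schema(6), 120, missing_rate = 0.08, seed = 5)
  ds <- generate(spec)
  expect_gt(count_missing(ds), 0)
  for (method in c("knn", "label_distribution")) {
    out <- impute_nulls(ds, preprocess_config(impute_method = method))
    expect_equal(count_missing(out$dataset), 0)
  }
})

test_that("outlier detection flags displaced points", {
  set.seed(3)
  x <- matrix(rnorm(100 * 3), 100, 3)
  x <- rbind(x, c(10, 10, 10))           # 10 SDs out on every axis
  ds <- toy_dataset(x, rep(0:1, length.out = 101))
  cfg <- preprocess_config(contamination = 0.01, seed = 1)
  mask <- detect_outliers(ds, cfg)
  expect_length(mask, 101)
  expect_equal(which(mask), 101L)
  # brute-force check: flagged point maximizes the robust distance
  dev <- apply(x, 1, function(r)
    sqrt(sum(((r - colMeans(x[1:100, ])) / apply(x[1:100, ], 2, sd))^2)))
  expect_equal(which.max(dev), 101L)

  # contamination 0 -> empty mask, no error
  expect_false(any(detect_outliers(ds, preprocess_config(contamination = 0))))
})

test_that("zscore outliers match hand-computed z-scores", {
  v <- c(0, 0, 0, 0, 100)
  ds <- toy_dataset(cbind(v, rep(1, 5)), c(0, 1, 0, 1, 0))
  mask <- detect_outliers(ds, preprocess_config(outlier_method = "zscore",
                                                zscore_threshold = 1.5))
  z5 <- (100 - mean(v)) / sd(v)          # 1.789
  expect_gt(abs(z5), 1.5)
  expect_equal(which(mask), 5L)
})

test_that("rebalancing equalizes class counts", {
  set.seed(2)
  ds <- toy_dataset(matrix(rnorm(200), 100, 2), rep(c(1, 0), c(60, 40)))
  over <- rebalance(ds, preprocess_config(rebalance_method = "oversample"))
  expect_equal(as.vector(table(dataset_labels(over))), c(60, 60))
  under <- rebalance(ds, preprocess_config(rebalance_method = "undersample"))
  expect_equal(as.vector(table(dataset_labels(under))), c(40, 40))
  balanced <- toy_dataset(matrix(rnorm(40), 20, 2), rep(0:1, 10))
  expect_equal(rebalance(balanced,
                         preprocess_config(rebalance_method = "oversample"))$data,
               balanced$data)
  oneclass <- toy_dataset(matrix(rnorm(20), 10, 2), rep(1, 10))
  expect_error_class(rebalance(oneclass,
                               preprocess_config(rebalance_method = "oversample")),
                     "degenerate_label_error")
})

test_that("K2 normality test matches independent reference values", {
  # reference statistics computed with scipy.stats.normaltest (frozen)
  a <- c(2.1, 3.5, 1.7, 4.2, 2.8, 3.1, 2.2, 5.0, 3.3, 2.9, 3.8, 1.9, 4.5, 3.0, 2.6)
  r <- dagostino_k2(a)
  expect_equal(r$statistic, 0.6884940349953993, tolerance = 1e-10)
  expect_equal(r$p.value, 0.7087538318264628, tolerance = 1e-10)
  r2 <- dagostino_k2(exp(seq(0, 3, length.out = 40)))
  expect_equal(r2$statistic, 6.946635241714299, tolerance = 1e-10)
  r3 <- dagostino_k2(sin(0:59) * 3 + (0:59) * 0.1)
  expect_equal(r3$statistic, 2.4940405358687014, tolerance = 1e-10)
  # strongly platykurtic data exercises the signed cube root in the kurtosis Z
  x4 <- c(rep(0, 30), rep(1, 30)) * 5 + seq(0, 1, length.out = 60)
  expect_equal(dagostino_k2(x4)$statistic, 821.2840006080929, tolerance = 1e-9)
  expect_error_class(dagostino_k2(1:5), "data_error")
})

test_that("scaling rule: normal -> standardize, non-normal -> max-scale", {
  set.seed(8)
  n <- 500
  normal_col <- rnorm(n, 50, 10)
  skew_col <- runif(n)^4                  # heavy right skew, non-normal
  const_col <- rep(7, n)
  ds <- toy_dataset(cbind(normal_col, skew_col, const_col),
                    rep(0:1, n / 2))
  plan <- fit_scalers(ds, preprocess_config())
  expect_equal(plan$f1$kind, "standardize")
  expect_equal(plan$f2$kind, "max_scale")
  expect_equal(plan$f3$kind, "constant")
  # the stated normality test drives the decision
  expect_gte(dagostino_k2(normal_col)$p.value, 0.05)
  expect_lt(dagostino_k2(skew_col)$p.value, 0.05)
  out <- apply_scalers(ds, plan)
  expect_equal(mean(out$data$f1), 0, tolerance = 1e-12)
  expect_equal(sd(out$data$f1), 1, tolerance = 1e-12)
  expect_true(all(out$data$f2 >= 0 & out$data$f2 <= 1))
  expect_true(all(out$data$f3 == 0))
})

test_that("skewed normal columns are log-transformed before standardizing", {
  set.seed(10)
  z <- rnorm(400)
  x <- exp(1.1 * z)                       # log-normal: skewed, log is normal
  ds <- toy_dataset(cbind(x, rnorm(400)), rep(0:1, 200))
  plan <- fit_scalers(ds, preprocess_config(normality_alpha = 0))
  # with alpha 0 every column passes the normality gate; the skew rule fires
  expect_equal(plan$f1$kind, "log_standardize")
  out <- apply_scalers(ds, plan)
  expect_equal(mean(out$data$f1), 0, tolerance = 1e-10)
})

test_that("the frozen plan is applied verbatim to unseen rows", {
  set.seed(12)
  train <- toy_dataset(cbind(rnorm(200, 50, 10), runif(200)^3),
                       rep(0:1, 100))
  plan <- fit_scalers(train, preprocess_config())
  test <- toy_dataset(cbind(c(50, 60), c(0.5, 0.9)), c(0, 1))
  out <- apply_scalers(test, plan)
  expect_equal(out$data$f1, (c(50, 60) - plan$f1$mean) / plan$f1$sd)
  expect_equal(out$data$f2, c(0.5, 0.9) / plan$f2$max)
  # plan record (not re-fitting) is the idempotence contract
  expect_named(plan, c("f1", "f2"))
})

test_that("the full pipeline runs in fixed order and reports consistent counts", {
  spec <- synthetic_spec(toy_schema(5), 260, informative_features = "f1",
                         effect_sizes = 1.5, missing_rate = 0.03,
                         duplicate_count = 6, outlier_count = 3, seed = 30)
  ds <- generate(spec)
  pp <- preprocess_fit(ds, preprocess_config(seed = 2))
  ops <- vapply(pp$dataset$transform_log, `[[`, "", "operation")
  expect_equal(ops, c("generate", "remove_duplicates", "impute_nulls",
                      "remove_outliers", "apply_scalers"))
  r <- pp$report
  expect_equal(n_rows(pp$dataset),
               n_rows(ds) - r$duplicates_removed - r$outliers_removed)
  expect_equal(count_missing(pp$dataset), 0)
  expect_length(r$column_transforms, 5)
  # byte-determinism of the whole pipeline
  pp2 <- preprocess_fit(ds, preprocess_config(seed = 2))
  expect_identical(pp$dataset$data, pp2$dataset$data)
})
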