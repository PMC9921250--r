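# Shared fixtures: everything is built in code at test time.

# minimal 3-column schema (age, sex, target)
mini_schema <- function() {
  dataset_schema(list(
    column_spec("age", "numeric_continuous", range = c(20, 90)),
    column_spec("sex", "binary"),
    column_spec("target", "binary")
  ), label_column = "target")
}

# n-feature all-continuous schema with a binary outcome
toy_schema <- function(n_feats, prefix = "f") {
  cols <- c(lapply(sprintf("%s%d", prefix, seq_len(n_feats)), column_spec,
                   type = "numeric_continuous"),
            list(column_spec("outcome", "binary")))
  dataset_schema(cols, label_column = "outcome")
}

# dataset from a plain matrix + labels
toy_dataset <- function(x, y, prefix = "f") {
  x <- as.matrix(x)
  sch <- toy_schema(ncol(x), prefix)
  d <- as.data.frame(x)
  names(d) <- sprintf("%s%d", prefix, seq_len(ncol(x)))
  d$outcome <- y
  tabular_dataset(d, sch)
}

# linearly separable two-feature dataset
separable_dataset <- function(n = 60, gap = 4, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x1 <- rnorm(n) + gap * y
  x2 <- rnorm(n) - gap * y
  toy_dataset(cbind(x1, x2), y)
}

# fast base-model configs for ensemble tests
fast_base_cfgs <- function(models = c("lr", "rf"), seed = 1) {
  cfgs <- lapply(models, function(m) switch(m,
    lr = base_model_config("lr", seed = seed),
    svm = base_model_config("svm", seed = seed),
    rf = base_model_config("rf", list(n_trees = 15L), seed = seed),
    xgb = base_model_config("xgb", list(n_rounds = 20L), seed = seed),
    dnn = base_model_config("dnn", list(epochs = 15L), seed = seed),
    cnn = base_model_config("cnn", list(epochs = 8L), seed = seed)))
  names(cfgs) <- models
  cfgs
}

# fake base outputs for combiner tests
fake_outputs <- function(classes, probs) {
  stopifnot(ncol(classes) == ncol(probs))
  out <- lapply(seq_len(ncol(classes)), function(j)
    list(class = classes[, j], prob = probs[, j]))
  names(out) <- paste0("m", seq_len(ncol(classes)))
  out
}

expect_error_class <- function(expr, class)
  expect_error(expr, class = class)
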