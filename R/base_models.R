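.base_model_defaults <- list(
  lr  = list(alpha = 0.1, fit_intercept = TRUE),
  svm = list(kernel = "rbf", cost = 1, gamma = "scale", degree = 3,
             max_train = 1000L),
  xgb = list(n_rounds = 100L, eta = 0.3, max_depth = 5L,
             min_split_loss = 0.001, max_delta_step = 0),
  rf  = list(n_trees = 60L, max_depth = 4L, min_sample_split = 10L,
             min_samples_leaf = 3L),
  dnn = list(hidden_layers = 3L, hidden_width = 32L, learning_rate = 0.01,
             epochs = 200L, batch = 32L, patience = 20L),
  cnn = list(num_filters1 = 32L, num_filters2 = 32L, num_filters3 = 64L,
             fc_size = 128L, learning_rate = 0.01, epochs = 200L,
             batch = 32L, patience = 20L))

#' Configure a first-layer base model
#'
#' Six heterogeneous classifiers are available; hyperparameters are validated
#' against a per-model whitelist, and unspecified ones take the published
#' defaults: `lr` (L2 logistic, alpha 0.1), `svm` (RBF kernel), `xgb`
#' (gradient-boosted trees, depth 5, min_split_loss 0.001), `rf` (60 trees,
#' depth 4, min split 10, min leaf 3), `dnn` (3 ReLU hidden layers, Adam, lr
#' 0.01) and `cnn` (1-D convnet, filters 32/32/64, dense 128, lr 0.01).
#'
#' @param model_id one of `"lr"`, `"svm"`, `"xgb"`, `"rf"`, `"dnn"`, `"cnn"`.
#' @param hyperparameters named list overriding the defaults.
#' @param tuning `"none"`, `"grid"` or `"random"`.
#' @param tuning_grid named list of candidate values per hyperparameter.
#' @param seed integer seed for all stochastic fitting.
#' @return object of class `base_model_config`.
#' @export
base_model_config <- function(model_id, hyperparameters = list(),
                              tuning = c("none", "grid", "random"),
                              tuning_grid = NULL, seed = 1L) {
  model_id <- match.arg(model_id, names(.base_model_defaults))
  defaults <- .base_model_defaults[[model_id]]
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown))
    abort(sprintf("unknown hyperparameter(s) for %s: %s", model_id,
                  paste(unknown, collapse = ", ")), "config_error")
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(model_id = model_id, hyperparameters = hp,
                 tuning = match.arg(tuning), tuning_grid = tuning_grid,
                 seed = as.integer(seed)),
            class = "base_model_config")
}

#' Train a first-layer base model
#'
#' @param ds a preprocessed [tabular_dataset()] (scaled, no missing cells)
#'   with both classes present.
#' @param cfg a [base_model_config()].
#' @return object of class `base_model` holding the fitted model and the
#'   training feature layout.
#' @export
train_base <- function(ds, cfg) {
  stopifnot(inherits(cfg, "base_model_config"))
  x <- feature_matrix(ds)
  y <- dataset_labels(ds)
  if (length(unique(y)) < 2)
    abort("training labels contain a single class", "degenerate_label_error")
  hp <- cfg$hyperparameters
  fit <- switch(cfg$model_id,
    lr  = ridge_logistic(x, y, alpha = hp$alpha),
    svm = {
      # kernel QP scales cubically; cap the training subsample (seeded)
      if (nrow(x) > hp$max_train) {
        keep <- with_seed(cfg$seed, sample(nrow(x), hp$max_train))
        svm_rbf(x[keep, , drop = FALSE], y[keep], cost = hp$cost,
                gamma = hp$gamma)
      } else svm_rbf(x, y, cost = hp$cost, gamma = hp$gamma)
    },
    xgb = gradient_boost(x, y, n_rounds = hp$n_rounds, eta = hp$eta,
                         max_depth = hp$max_depth,
                         min_split_loss = hp$min_split_loss,
                         max_delta_step = hp$max_delta_step, seed = cfg$seed),
    rf  = random_forest(x, y, n_trees = hp$n_trees, max_depth = hp$max_depth,
                        min_split = hp$min_sample_split,
                        min_leaf = hp$min_samples_leaf, seed = cfg$seed),
    dnn = mlp_fit(x, y, hidden = rep(hp$hidden_width, hp$hidden_layers),
                  lr = hp$learning_rate, epochs = hp$epochs, batch = hp$batch,
                  patience = hp$patience, seed = cfg$seed),
    cnn = cnn_fit(x, y,
                  filters = c(hp$num_filters1, hp$num_filters2, hp$num_filters3),
                  fc_size = hp$fc_size, lr = hp$learning_rate,
                  epochs = hp$epochs, batch = hp$batch,
                  patience = hp$patience, seed = cfg$seed))
  structure(list(model_id = cfg$model_id, fit = fit, config = cfg,
                 feature_layout = colnames(x)),
            class = "base_model")
}

#' Predict classes and positive probabilities from a base model
#'
#' The class decision is `indicator(probability >= 0.5)` for every model, so
#' class/probability consistency holds by construction.
#' @param model a fitted `base_model`.
#' @param rows a [tabular_dataset()] or numeric matrix conforming to the
#'   training feature layout.
#' @return `list(class = 0/1 vector, prob = [0,1] vector)`.
#' @export
predict_base <- function(model, rows) {
  stopifnot(inherits(model, "base_model"))
  x <- if (inherits(rows, "tabular_dataset")) feature_matrix(rows)
       else as.matrix(rows)
  if (!identical(colnames(x), model$feature_layout))
    abort("prediction features do not match the training layout",
          "feature_mismatch_error")
  p <- if (model$model_id == "lr") predict_ridge_logistic(model$fit, x)
       else predict(model$fit, x)
  p <- pmin(pmax(as.numeric(p), 0), 1)
  list(class = as.integer(p >= 0.5), prob = p)
}

#' Tune a base model over a hyperparameter grid
#'
#' `"grid"` evaluates every cell of `tuning_grid` exhaustively; `"random"`
#' draws a fixed seeded budget of cells. Each candidate is scored by mean
#' stratified k-fold CV accuracy; ties go to the first candidate in the
#' deterministic iteration order. Candidates whose fit fails are recorded in
#' the `errors` attribute of the result and skipped.
#'
#' @param ds a preprocessed [tabular_dataset()].
#' @param cfg a [base_model_config()] with `tuning != "none"` and a non-empty
#'   `tuning_grid`.
#' @param k CV folds for scoring (default 5).
#' @param budget random-search draws (default 10).
#' @return the winning [base_model_config()] (with `tuning = "none"`), with
#'   attributes `cv_accuracy` and `errors`.
#' @export
tune <- function(ds, cfg, k = 5L, budget = 10L) {
  if (cfg$tuning == "none") abort("cfg$tuning is 'none'", "argument_error")
  if (is.null(cfg$tuning_grid) || !length(cfg$tuning_grid))
    abort("empty tuning grid", "argument_error")
  grid <- expand.grid(cfg$tuning_grid, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  if (cfg$tuning == "random") {
    pick <- with_seed(cfg$seed, sample(nrow(grid), min(budget, nrow(grid))))
    grid <- grid[sort(pick), , drop = FALSE]
  }
  y <- dataset_labels(ds)
  folds <- stratified_kfold(y, k = min(k, min(table(y))), seed = cfg$seed)
  best <- NULL; best_acc <- -Inf; errors <- list()
  for (i in seq_len(nrow(grid))) {
    hp <- utils::modifyList(cfg$hyperparameters, as.list(grid[i, , drop = FALSE]))
    cand <- try(base_model_config(cfg$model_id, hp, seed = cfg$seed),
                silent = TRUE)
    if (inherits(cand, "try-error")) {
      errors[[length(errors) + 1]] <- list(cell = i, error = as.character(cand))
      next
    }
    accs <- rep(NA_real_, max(folds))
    ok <- TRUE
    for (f in seq_len(max(folds))) {
      tr <- subset_rows(ds, folds != f); te <- subset_rows(ds, folds == f)
      m <- try(train_base(tr, cand), silent = TRUE)
      if (inherits(m, "try-error")) { ok <- FALSE
        errors[[length(errors) + 1]] <- list(cell = i, error = as.character(m))
        break }
      accs[f] <- mean(predict_base(m, te)$class == dataset_labels(te))
    }
    if (ok && mean(accs) > best_acc) { best_acc <- mean(accs); best <- cand }
  }
  if (is.null(best)) abort("no tuning candidate could be fitted", "config_error")
  attr(best, "cv_accuracy") <- best_acc
  attr(best, "errors") <- errors
  best
}

#' Subset the rows of a dataset
#' @param ds a [tabular_dataset()]; @param keep logical or integer row index.
#' @export
subset_rows <- function(ds, keep) {
  out <- ds
  out$data <- ds$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}
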