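#' Assemble the meta-feature matrix from base-model outputs
#'
#' Probability-augmented layout: for M base models in `model_order`, the
#' matrix is n x 2M with columns `(class_1, p_1, class_2, p_2, ...)`. Only
#' the positive-class probability enters (the negative one is collinear).
#'
#' @param outputs named list: model_id -> `list(class, prob)` as returned by
#'   [predict_base()].
#' @param model_order character vector fixing the column block order.
#' @param include one of `"both"` (proposed stacking) or `"class"` (classical
#'   stacking, class columns only).
#' @return numeric matrix with named columns.
#' @export
build_meta_features <- function(outputs, model_order,
                                include = c("both", "class")) {
  include <- match.arg(include)
  missing_m <- setdiff(model_order, names(outputs))
  if (length(missing_m))
    abort(paste("missing base model output(s):",
                paste(missing_m, collapse = ", ")), "ensemble_mismatch_error")
  blocks <- lapply(model_order, function(m) {
    o <- outputs[[m]]
    if (include == "both")
      matrix(c(o$class, o$prob), ncol = 2,
             dimnames = list(NULL, paste0(c("class_", "p_"), m)))
    else matrix(as.numeric(o$class), ncol = 1,
                dimnames = list(NULL, paste0("class_", m)))
  })
  do.call(cbind, blocks)
}

.oof_outputs <- function(ds, base_cfgs, oof_folds, seed) {
  y <- dataset_labels(ds)
  folds <- stratified_kfold(y, k = oof_folds, seed = seed)
  n <- length(y)
  outputs <- lapply(base_cfgs, function(cfg)
    list(class = integer(n), prob = numeric(n)))
  for (f in seq_len(oof_folds)) {
    hold <- folds == f
    tr <- subset_rows(ds, !hold)
    te <- subset_rows(ds, hold)
    for (m in names(base_cfgs)) {
      fit <- train_base(tr, base_cfgs[[m]])
      pr <- predict_base(fit, te)
      outputs[[m]]$class[hold] <- pr$class
      outputs[[m]]$prob[hold] <- pr$prob
    }
  }
  list(outputs = outputs, folds = folds)
}

#' Fit the two-layer stacking classifier
#'
#' First layer: the configured base models. Their training-time outputs are
#' produced OUT-OF-FOLD over `oof_folds` stratified splits, so no meta-feature
#' of a row comes from a base model whose training fold contained that row;
#' the bases are then refit on all rows for deployment. Second layer: a
#' logistic model on the meta-features — both class decisions and decision
#' probabilities for the proposed architecture, class decisions only for the
#' classical baseline ([fit_classical_stack()]).
#'
#' @param ds a preprocessed [tabular_dataset()].
#' @param base_cfgs named list of [base_model_config()]s (names = model ids,
#'   fixing the meta column order).
#' @param oof_folds out-of-fold splits (>= 2; default 5).
#' @param seed seed for the fold assignment.
#' @param meta_features `"both"` (proposed) or `"class"` (classical).
#' @param in_sample if `TRUE`, train the meta layer on in-sample base
#'   predictions instead of out-of-fold ones (leaky; provided for protocol
#'   comparison only).
#' @return object of class `stacked_model` with the fitted bases, the meta
#'   logistic model, and the training protocol record.
#' @export
fit_stacked <- function(ds, base_cfgs, oof_folds = 5L, seed = 1L,
                        meta_features = c("both", "class"),
                        in_sample = FALSE) {
  meta_features <- match.arg(meta_features)
  if (is.null(names(base_cfgs)) || any(!nzchar(names(base_cfgs))))
    names(base_cfgs) <- vapply(base_cfgs, `[[`, "", "model_id")
  if (oof_folds < 2) abort("oof_folds must be >= 2", "argument_error")
  model_order <- names(base_cfgs)
  y <- dataset_labels(ds)
  bases <- lapply(base_cfgs, function(cfg) train_base(ds, cfg))
  if (in_sample) {
    outputs <- lapply(bases, predict_base, rows = ds)
    folds <- NULL
  } else {
    oof <- .oof_outputs(ds, base_cfgs, oof_folds, seed)
    outputs <- oof$outputs
    folds <- oof$folds
  }
  mf <- build_meta_features(outputs, model_order, include = meta_features)
  meta <- ridge_logistic(mf, y, alpha = 0.1)
  structure(list(bases = bases, meta = meta, model_order = model_order,
                 meta_features = meta_features,
                 meta_width = ncol(mf),
                 protocol = list(oof_folds = if (in_sample) NA_integer_ else oof_folds,
                                 seed = seed, in_sample = in_sample,
                                 fold_assignment = folds)),
            class = "stacked_model")
}

#' @rdname fit_stacked
#' @export
fit_classical_stack <- function(ds, base_cfgs, oof_folds = 5L, seed = 1L,
                                in_sample = FALSE)
  fit_stacked(ds, base_cfgs, oof_folds = oof_folds, seed = seed,
              meta_features = "class", in_sample = in_sample)

#' Predict with a fitted stacking classifier
#'
#' Runs every base model, assembles the meta-features in the training column
#' layout, and returns the meta-logistic decision at threshold 0.5 together
#' with the meta probability as the framework's confidence.
#' @param sm a `stacked_model`.
#' @param rows a [tabular_dataset()] or feature matrix.
#' @return `list(class, prob)`.
#' @export
predict_stacked <- function(sm, rows) {
  stopifnot(inherits(sm, "stacked_model"))
  outputs <- lapply(sm$bases, predict_base, rows = rows)
  mf <- build_meta_features(outputs, sm$model_order,
                            include = sm$meta_features)
  if (ncol(mf) != sm$meta_width)
    abort("meta-feature width mismatch", "ensemble_mismatch_error")
  p <- predict_ridge_logistic(sm$meta, mf)
  list(class = as.integer(p >= 0.5), prob = p)
}

#' Traditional majority voting over base-model outputs
#'
#' Per row, the class with the strictly greater count of base-model votes
#' wins; a count tie (even M) is broken by the mean positive probability
#' across models (> 0.5 votes positive), and an exact tie of both goes to
#' class 1.
#' @param outputs named list of `list(class, prob)` per model (M >= 1).
#' @return integer 0/1 class vector.
#' @export
majority_vote <- function(outputs) {
  if (!length(outputs)) abort("no base outputs", "argument_error")
  cls <- vapply(outputs, function(o) as.numeric(o$class),
                numeric(length(outputs[[1]]$class)))
  prb <- vapply(outputs, function(o) as.numeric(o$prob),
                numeric(length(outputs[[1]]$prob)))
  if (is.null(dim(cls))) { cls <- matrix(cls, nrow = 1); prb <- matrix(prb, nrow = 1) }
  ones <- rowSums(cls)
  m <- ncol(cls)
  out <- integer(nrow(cls))
  out[ones > m / 2] <- 1L
  tie <- ones == m / 2
  if (any(tie)) {
    mp <- rowMeans(prb)[tie]
    out[tie] <- ifelse(mp >= 0.5, 1L, 0L)
  }
  out
}
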