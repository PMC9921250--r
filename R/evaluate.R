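#' Confusion counts for binary predictions
#'
#' Positive class = 1: `tp` true in both reality and prediction, `fp` false
#' in reality but predicted true, `fn` true in reality but predicted false,
#' `tn` false in both. The counts always satisfy `tp + fp + fn + tn = N`.
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return object of class `confusion_counts`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    abort("y_true and y_pred must have equal length", "label_error")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    abort("labels must be binary 0/1", "label_error")
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == 0),
                 tn = sum(y_true == 0 & y_pred == 0)),
            class = "confusion_counts")
}

#' Evaluation metrics from confusion counts
#'
#' Accuracy `(TP+TN)/N`, specificity `TN/(FP+TN)`, sensitivity (recall)
#' `TP/(FN+TP)`, precision `TP/(TP+FP)`, and F1 = harmonic mean of recall and
#' precision. A zero denominator makes the metric undefined: it is reported
#' as `NA` and its name is listed in the `undefined` field — never silently
#' coerced to 0.
#'
#' @param counts a `confusion_counts` object.
#' @return object of class `evaluation_metrics`.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n <- tp + fp + fn + tn
  if (n < 1) abort("empty confusion counts", "argument_error")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, fn + tp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(prec) || (sens + prec) == 0) NA_real_
        else 2 * sens * prec / (sens + prec)
  vals <- list(accuracy = (tp + tn) / n,
               specificity = ratio(tn, fp + tn),
               sensitivity = sens,
               precision = prec,
               f1 = f1)
  undefined <- names(vals)[vapply(vals, is.na, logical(1))]
  structure(c(vals, list(counts = counts, undefined = undefined)),
            class = "evaluation_metrics")
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat(sprintf("<evaluation_metrics> acc %.3f | spec %s | sens %s | prec %s | f1 %s\n",
              x$accuracy,
              formatC(x$specificity, digits = 3, format = "f"),
              formatC(x$sensitivity, digits = 3, format = "f"),
              formatC(x$precision, digits = 3, format = "f"),
              formatC(x$f1, digits = 3, format = "f")))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Rows of each class are shuffled (seeded) and dealt round-robin over the
#' folds, so folds partition the rows and preserve class proportions.
#' @param y 0/1 label vector.
#' @param k number of folds (>= 2); each class needs at least k members.
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1:k`, one per row.
#' @export
stratified_kfold <- function(y, k = 10L, seed = 1L) {
  if (k < 2) abort("k must be >= 2", "argument_error")
  tab <- table(factor(y, levels = 0:1))
  if (any(tab < k))
    abort(sprintf("each class needs >= k members (counts %s, k=%d)",
                  paste(tab, collapse = "/"), k), "stratification_error")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

.fit_predict_combiner <- function(train, test, base_cfgs, combiner,
                                  oof_folds, seed) {
  if (combiner %in% c("proposed", "classical")) {
    sm <- fit_stacked(train, base_cfgs, oof_folds = oof_folds, seed = seed,
                      meta_features = if (combiner == "proposed") "both" else "class")
    predict_stacked(sm, test)$class
  } else if (combiner == "majority") {
    bases <- lapply(base_cfgs, function(cfg) train_base(train, cfg))
    majority_vote(lapply(bases, predict_base, rows = test))
  } else if (startsWith(combiner, "single:")) {
    id <- sub("^single:", "", combiner)
    if (!id %in% names(base_cfgs))
      abort(paste("unknown single model:", id), "config_error")
    predict_base(train_base(train, base_cfgs[[id]]), test)$class
  } else abort(paste("unknown combiner:", combiner), "config_error")
}

#' Stratified k-fold cross-validation of a classification pipeline
#'
#' For every fold, preprocessing (when configured) is fitted on the training
#' partitions only and its frozen plan applied to the held-out partition;
#' the combiner is then trained on the processed training rows and evaluated
#' on the held-out rows. Fold metrics are averaged unweighted; undefined
#' fold metrics are excluded from the mean with a warning.
#'
#' @param ds a [tabular_dataset()].
#' @param base_cfgs named list of [base_model_config()]s.
#' @param combiner `"proposed"`, `"classical"`, `"majority"` or
#'   `"single:<model_id>"`.
#' @param k folds (default 10); @param seed fold/pipeline seed.
#' @param preprocess optional [preprocess_config()]; `NULL` skips the
#'   pipeline (raw features).
#' @param oof_folds out-of-fold splits for the stacking meta layer.
#' @return object of class `cv_result` with `per_fold`, `mean_metrics`,
#'   `fold_assignment`, `k`, `seed`.
#' @export
cross_validate <- function(ds, base_cfgs, combiner = "proposed", k = 10L,
                           seed = 1L, preprocess = NULL, oof_folds = 5L) {
  y <- dataset_labels(ds)
  folds <- stratified_kfold(y, k = k, seed = seed)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- subset_rows(ds, folds != f)
    te <- subset_rows(ds, folds == f)
    if (!is.null(preprocess)) {
      pp <- preprocess_fit(tr, preprocess)
      tr <- pp$dataset
      te <- preprocess_apply(te, pp$plan)
    }
    pred <- .fit_predict_combiner(tr, te, base_cfgs, combiner, oof_folds, seed)
    per_fold[[f]] <- metrics(confusion(dataset_labels(te), pred))
  }
  metric_names <- c("accuracy", "specificity", "sensitivity", "precision", "f1")
  mean_metrics <- vapply(metric_names, function(mn) {
    v <- vapply(per_fold, `[[`, numeric(1), mn)
    if (anyNA(v))
      warning(sprintf("metric '%s' undefined in %d fold(s); excluded from mean",
                      mn, sum(is.na(v))), call. = FALSE)
    mean(v, na.rm = TRUE)
  }, numeric(1))
  structure(list(k = k, per_fold = per_fold, mean_metrics = mean_metrics,
                 fold_assignment = folds, seed = seed, combiner = combiner),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold (seed %d)\n", x$combiner, x$k, x$seed))
  print(round(x$mean_metrics, 4))
  invisible(x)
}

#' Cross-validate several combiners over shared base-model computations
#'
#' Runs one stratified k-fold loop in which the base models are trained (and
#' their out-of-fold meta-features computed) once per fold, then evaluates
#' every requested combiner on those shared artifacts — the comparison design
#' of the framework study: identical base outputs, different consolidation.
#'
#' @inheritParams cross_validate
#' @param combiners character vector drawn from `"proposed"`, `"classical"`,
#'   `"majority"`, `"single:<model_id>"`.
#' @return named list of `cv_result` objects, one per combiner.
#' @export
compare_combiners <- function(ds, base_cfgs,
                              combiners = c("proposed", "classical", "majority"),
                              k = 10L, seed = 1L, preprocess = NULL,
                              oof_folds = 5L) {
  y <- dataset_labels(ds)
  folds <- stratified_kfold(y, k = k, seed = seed)
  needs_oof <- any(combiners %in% c("proposed", "classical"))
  preds <- lapply(combiners, function(cc) integer(length(y)))
  names(preds) <- combiners
  for (f in seq_len(k)) {
    tr <- subset_rows(ds, folds != f)
    te <- subset_rows(ds, folds == f)
    if (!is.null(preprocess)) {
      pp <- preprocess_fit(tr, preprocess)
      tr <- pp$dataset
      te <- preprocess_apply(te, pp$plan)
    }
    ytr <- dataset_labels(tr)
    bases <- lapply(base_cfgs, function(cfg) train_base(tr, cfg))
    test_out <- lapply(bases, predict_base, rows = te)
    oof <- if (needs_oof) .oof_outputs(tr, base_cfgs, oof_folds, seed)
    for (cc in combiners) {
      preds[[cc]][folds == f] <- if (cc %in% c("proposed", "classical")) {
        mode <- if (cc == "proposed") "both" else "class"
        meta <- ridge_logistic(
          build_meta_features(oof$outputs, names(base_cfgs), mode), ytr,
          alpha = 0.1)
        as.integer(predict_ridge_logistic(
          meta, build_meta_features(test_out, names(base_cfgs), mode)) >= 0.5)
      } else if (cc == "majority") {
        majority_vote(test_out)
      } else if (startsWith(cc, "single:")) {
        id <- sub("^single:", "", cc)
        if (!id %in% names(base_cfgs))
          abort(paste("unknown single model:", id), "config_error")
        test_out[[id]]$class
      } else abort(paste("unknown combiner:", cc), "config_error")
    }
  }
  lapply(preds, function(p) {
    per_fold <- lapply(seq_len(k), function(f)
      metrics(confusion(y[folds == f], p[folds == f])))
    metric_names <- c("accuracy", "specificity", "sensitivity", "precision", "f1")
    mean_metrics <- vapply(metric_names, function(mn)
      mean(vapply(per_fold, `[[`, numeric(1), mn), na.rm = TRUE), numeric(1))
    structure(list(k = k, per_fold = per_fold, mean_metrics = mean_metrics,
                   fold_assignment = folds, seed = seed, combiner = "shared"),
              class = "cv_result")
  })
}

#' Framework comparison reports
#'
#' `mode = "table4"`: cross-validates the proposed probability-augmented
#' stacker, traditional majority voting, classical (class-only) stacking and
#' every single base model, reporting the three combiners plus the best
#' single model — four rows. `mode = "table3"`: every base model with and
#' without the preprocessing pipeline — `2 * M` rows. Accuracy is reported in
#' percent, specificity/sensitivity as fractions.
#'
#' @param ds a [tabular_dataset()].
#' @param base_cfgs named list of [base_model_config()]s.
#' @param mode `"table4"` or `"table3"`.
#' @param k,seed,preprocess,oof_folds as in [cross_validate()].
#' @return data frame with columns `model`, `condition`, `accuracy`,
#'   `specificity`, `sensitivity`.
#' @export
compare_frameworks <- function(ds, base_cfgs, mode = c("table4", "table3"),
                               k = 10L, seed = 1L,
                               preprocess = preprocess_config(),
                               oof_folds = 5L) {
  mode <- match.arg(mode)
  row_of <- function(model, condition, cv)
    data.frame(model = model, condition = condition,
               accuracy = 100 * cv$mean_metrics[["accuracy"]],
               specificity = cv$mean_metrics[["specificity"]],
               sensitivity = cv$mean_metrics[["sensitivity"]])
  if (mode == "table3") {
    rows <- list()
    for (cond in c("without_preprocessing", "with_preprocessing")) {
      pp <- if (cond == "with_preprocessing") preprocess else NULL
      for (m in names(base_cfgs))
        rows[[paste(m, cond)]] <- row_of(m, cond,
          cross_validate(ds, base_cfgs, paste0("single:", m), k = k,
                         seed = seed, preprocess = pp, oof_folds = oof_folds))
    }
    out <- do.call(rbind, rows)
  } else {
    all_c <- c("proposed", "majority", "classical",
               paste0("single:", names(base_cfgs)))
    res <- compare_combiners(ds, base_cfgs, combiners = all_c, k = k,
                             seed = seed, preprocess = preprocess,
                             oof_folds = oof_folds)
    singles <- res[paste0("single:", names(base_cfgs))]
    accs <- vapply(singles, function(cv) cv$mean_metrics[["accuracy"]],
                   numeric(1))
    best <- names(base_cfgs)[which.max(accs)]
    out <- rbind(
      row_of("proposed_framework", "stacking_with_probabilities",
             res$proposed),
      row_of("traditional_voting", "majority_vote", res$majority),
      row_of("classical_stacking", "stacking_classes_only", res$classical),
      row_of(paste0("best_single:", best), "single_model",
             singles[[paste0("single:", best)]]))
  }
  rownames(out) <- NULL
  out
}
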