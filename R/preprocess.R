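#' Preprocessing configuration
#'
#' Controls the automated pipeline, which always runs in the fixed order
#' duplicates -> imputation -> outlier removal -> rebalancing -> scaling.
#'
#' @param impute_method `"knn"` (default, k nearest fully-comparable rows) or
#'   `"label_distribution"` (per-label-class mean/mode; training time only,
#'   since it reads labels).
#' @param knn_k neighbours for KNN imputation (default 5).
#' @param outlier_method `"isolation_forest"` (default), `"zscore"` or
#'   `"dbscan"`.
#' @param contamination assumed outlier fraction in [0, 0.5); rows with the
#'   highest anomaly scores are removed (default 0.05).
#' @param zscore_threshold |z| cutoff for the zscore method (default 3).
#' @param rebalance_method `"none"` (default), `"oversample"` or
#'   `"undersample"`.
#' @param normality_alpha significance level of the K2 normality test that
#'   chooses standardize vs max-scale (default 0.05).
#' @param skew_threshold |skewness| above which a normal column is
#'   log-transformed before standardization (default 1).
#' @param if_trees,if_sample_size isolation-forest ensemble size and
#'   sub-sample size (defaults 100 trees, 256).
#' @param seed RNG seed for all stochastic stages.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(impute_method = c("knn", "label_distribution"),
                              knn_k = 5L,
                              outlier_method = c("isolation_forest", "zscore", "dbscan"),
                              contamination = 0.05,
                              zscore_threshold = 3,
                              rebalance_method = c("none", "oversample", "undersample"),
                              normality_alpha = 0.05,
                              skew_threshold = 1,
                              if_trees = 100L,
                              if_sample_size = 256L,
                              seed = 1L) {
  if (contamination < 0 || contamination >= 0.5)
    abort("contamination must lie in [0, 0.5)", "config_error")
  if (knn_k < 1) abort("knn_k must be >= 1", "config_error")
  structure(list(impute_method = match.arg(impute_method),
                 knn_k = as.integer(knn_k),
                 outlier_method = match.arg(outlier_method),
                 contamination = contamination,
                 zscore_threshold = zscore_threshold,
                 rebalance_method = match.arg(rebalance_method),
                 normality_alpha = normality_alpha,
                 skew_threshold = skew_threshold,
                 if_trees = as.integer(if_trees),
                 if_sample_size = as.integer(if_sample_size),
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Remove duplicate rows
#'
#' Rows are duplicates when all feature values AND the label agree; only the
#' first occurrence survives, in the original order.
#' @param ds a [tabular_dataset()].
#' @return `list(dataset, count)` with the number of rows removed.
#' @export
remove_duplicates <- function(ds) {
  dup <- duplicated(ds$data)
  out <- ds
  out$data <- ds$data[!dup, , drop = FALSE]
  rownames(out$data) <- NULL
  out <- log_transform_op(out, "remove_duplicates", list(removed = sum(dup)))
  list(dataset = out, count = sum(dup))
}

.col_fill_value <- function(v, type) {
  obs <- v[!is.na(v)]
  if (type == "numeric_continuous") mean(obs)
  else {          # mode, first-seen tie-break
    tab <- table(obs)
    as.numeric(names(tab)[which.max(tab)])
  }
}

#' Impute missing feature cells
#'
#' `"knn"` fills a cell with the mean (continuous) or mode (other types) of
#' the `knn_k` nearest rows that observe that column, under Euclidean
#' distance on the numeric features observed in both rows (averaged per
#' shared feature so partial overlap is comparable). `"label_distribution"`
#' fills with the per-label-class column mean/mode.
#'
#' @param ds a [tabular_dataset()].
#' @param cfg a [preprocess_config()].
#' @return `list(dataset, count)` with the number of cells imputed.
#' @export
impute_nulls <- function(ds, cfg = preprocess_config()) {
  feats <- feature_names(ds$schema)
  d <- ds$data
  n_missing <- sum(is.na(d[, feats, drop = FALSE]))
  if (n_missing == 0)
    return(list(dataset = ds, count = 0L))
  fully_missing <- feats[vapply(feats, function(f) all(is.na(d[[f]])), logical(1))]
  if (length(fully_missing))
    abort(paste("column(s) entirely missing, cannot impute:",
                paste(fully_missing, collapse = ", ")), "unimputable_column_error")
  types <- vapply(feats, function(f) schema_col(ds$schema, f)$type, character(1))
  numf <- feats[types %in% c("numeric_continuous", "numeric_ordinal")]
  if (cfg$impute_method == "label_distribution") {
    y <- dataset_labels(ds)
    for (f in feats) {
      miss <- which(is.na(d[[f]]))
      for (r in miss) {
        same <- d[[f]][y == y[r]]
        v <- if (all(is.na(same))) .col_fill_value(d[[f]], types[f])
             else .col_fill_value(same, types[f])
        d[r, f] <- v
      }
    }
  } else {
    xm <- as.matrix(d[, numf, drop = FALSE])
    for (f in feats) {
      miss <- which(is.na(d[[f]]))
      for (r in miss) {
        donors <- which(!is.na(ds$data[[f]]))
        donors <- donors[donors != r]
        # mean squared difference over shared observed numeric features
        dist2 <- vapply(donors, function(q) {
          shared <- !is.na(xm[r, ]) & !is.na(xm[q, ])
          if (!any(shared)) return(Inf)
          mean((xm[r, shared] - xm[q, shared])^2)
        }, numeric(1))
        ord <- order(dist2, donors)
        nb <- donors[ord[seq_len(min(cfg$knn_k, length(donors)))]]
        d[r, f] <- .col_fill_value(ds$data[[f]][nb], types[f])
      }
    }
  }
  out <- ds
  out$data <- d
  out <- log_transform_op(out, "impute_nulls",
                          list(method = cfg$impute_method, cells = n_missing))
  list(dataset = out, count = n_missing)
}

#' Flag outlying rows
#'
#' `"isolation_forest"` scores rows with [isolation_forest_score()] and flags
#' the `contamination` fraction with the highest anomaly scores;
#' `"zscore"` flags rows with any per-column |z| above `zscore_threshold`;
#' `"dbscan"` flags density-based noise points (not within `eps` of any core
#' point; `eps` taken as the 90th percentile of k-nearest-neighbour
#' distances, `minPts = 5`).
#'
#' @param ds a [tabular_dataset()] with no missing feature cells.
#' @param cfg a [preprocess_config()].
#' @return logical mask over rows, `TRUE` = outlier.
#' @export
detect_outliers <- function(ds, cfg = preprocess_config()) {
  n <- n_rows(ds)
  x <- feature_matrix(ds)
  if (cfg$outlier_method == "zscore") {
    z <- scale(x)
    z[is.nan(z)] <- 0
    return(apply(abs(z) > cfg$zscore_threshold, 1, any))
  }
  if (cfg$outlier_method == "dbscan") {
    dm <- as.matrix(dist(scale(x)))
    minPts <- 5L
    kdist <- apply(dm, 1, function(r) sort(r)[min(minPts + 1L, n)])
    eps <- quantile(kdist, 0.9)
    ncount <- rowSums(dm <= eps)
    core <- ncount >= minPts
    reach <- apply(dm[, core, drop = FALSE] <= eps, 1, any)
    return(!(core | reach))
  }
  if (cfg$contamination == 0) return(rep(FALSE, n))
  if (n < 8) abort("isolation_forest needs >= 8 rows", "data_error")
  sc <- isolation_forest_score(x, n_trees = cfg$if_trees,
                               sample_size = cfg$if_sample_size,
                               seed = cfg$seed)
  k <- floor(cfg$contamination * n)
  mask <- rep(FALSE, n)
  if (k > 0) mask[order(-sc, seq_len(n))[seq_len(k)]] <- TRUE
  mask
}

#' Rebalance class labels
#'
#' Oversampling duplicates seeded-random minority rows (with replacement)
#' until class counts are equal; undersampling drops seeded-random majority
#' rows; `"none"` is the identity.
#' @param ds a [tabular_dataset()].
#' @param cfg a [preprocess_config()].
#' @return a rebalanced [tabular_dataset()].
#' @export
rebalance <- function(ds, cfg = preprocess_config()) {
  if (cfg$rebalance_method == "none") return(ds)
  y <- dataset_labels(ds)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("one class absent", "degenerate_label_error")
  if (n1 == n0) return(ds)
  minority <- if (n1 < n0) 1 else 0
  with_seed(cfg$seed, {
    d <- ds$data
    if (cfg$rebalance_method == "oversample") {
      idx <- which(y == minority)
      extra <- sample(idx, abs(n1 - n0), replace = TRUE)
      d <- rbind(d, d[extra, , drop = FALSE])
    } else {
      maj <- which(y != minority)
      drop_idx <- sample(maj, abs(n1 - n0))
      d <- d[-drop_idx, , drop = FALSE]
    }
    rownames(d) <- NULL
    out <- ds
    out$data <- d
    log_transform_op(out, "rebalance", list(method = cfg$rebalance_method))
  })
}

#' Fit and apply the distribution-aware scaling plan
#'
#' Per numeric non-label column, fitted on training rows only: a K2 normality
#' test at `normality_alpha` decides standardize (normal) vs scale-by-maximum
#' (non-normal); among normal columns, |skewness| above `skew_threshold`
#' triggers `log(1 + x - min(x))` before standardization. Binary and
#' categorical columns are untouched; constant columns map to 0. Columns with
#' fewer than 8 observations are treated as non-normal (the K2 test is
#' undefined there). The plan is frozen at fit time and reapplied verbatim to
#' unseen rows.
#'
#' @param ds a [tabular_dataset()] of training rows, fully imputed.
#' @param cfg a [preprocess_config()].
#' @return `fit_scalers`: a `scaler_plan` (named per-column records);
#'   `apply_scalers`: the transformed dataset.
#' @export
fit_scalers <- function(ds, cfg = preprocess_config()) {
  feats <- feature_names(ds$schema)
  plan <- list()
  for (f in feats) {
    cs <- schema_col(ds$schema, f)
    x <- ds$data[[f]]
    if (!cs$type %in% c("numeric_continuous", "numeric_ordinal")) {
      plan[[f]] <- list(kind = "untouched")
      next
    }
    if (length(unique(x)) == 1L) {
      plan[[f]] <- list(kind = "constant", value = x[1])
      next
    }
    normal <- if (length(x) >= 8) dagostino_k2(x)$p.value >= cfg$normality_alpha
              else FALSE
    if (!normal) {
      mx <- max(x)
      if (mx == 0) mx <- max(abs(x))
      plan[[f]] <- list(kind = "max_scale", max = mx)
    } else if (abs(sample_skewness(x)) > cfg$skew_threshold) {
      off <- min(x)
      lx <- log(1 + x - off)
      plan[[f]] <- list(kind = "log_standardize", offset = off,
                        mean = mean(lx), sd = sd(lx))
    } else {
      plan[[f]] <- list(kind = "standardize", mean = mean(x), sd = sd(x))
    }
  }
  structure(plan, class = "scaler_plan")
}

#' @rdname fit_scalers
#' @param plan a frozen `scaler_plan` from [fit_scalers()].
#' @export
apply_scalers <- function(ds, plan) {
  stopifnot(inherits(plan, "scaler_plan"))
  d <- ds$data
  for (f in names(plan)) {
    p <- plan[[f]]
    d[[f]] <- switch(p$kind,
      untouched = d[[f]],
      constant = rep(0, nrow(d)),
      max_scale = d[[f]] / p$max,
      standardize = (d[[f]] - p$mean) / p$sd,
      log_standardize = (log(1 + d[[f]] - p$offset) - p$mean) / p$sd)
  }
  out <- ds
  out$data <- d
  log_transform_op(out, "apply_scalers",
                   list(plan = vapply(plan, `[[`, "", "kind")))
}

#' Run the full preprocessing pipeline on training data
#'
#' Fixed stage order: duplicate removal -> imputation -> outlier removal ->
#' rebalancing -> scaler fit + apply. Returns the processed dataset, a frozen
#' transform plan for unseen rows, and a report of the counts at every stage.
#'
#' @param ds a [tabular_dataset()] of training rows.
#' @param cfg a [preprocess_config()].
#' @return list with `dataset`, `plan` (class `preprocess_plan`: scaler plan +
#'   per-column fallback fill values for unseen-row imputation), and `report`
#'   (class `preprocess_report`).
#' @export
preprocess_fit <- function(ds, cfg = preprocess_config()) {
  counts_before <- table(factor(dataset_labels(ds), levels = 0:1))
  dup <- remove_duplicates(ds)
  imp <- impute_nulls(dup$dataset, cfg)
  mask <- detect_outliers(imp$dataset, cfg)
  cur <- imp$dataset
  if (any(mask)) {
    cur$data <- cur$data[!mask, , drop = FALSE]
    rownames(cur$data) <- NULL
    cur <- log_transform_op(cur, "remove_outliers",
                            list(method = cfg$outlier_method, removed = sum(mask)))
  }
  cur <- rebalance(cur, cfg)
  plan <- fit_scalers(cur, cfg)
  feats <- feature_names(cur$schema)
  types <- vapply(feats, function(f) schema_col(cur$schema, f)$type, character(1))
  fallback <- setNames(lapply(feats, function(f)
    .col_fill_value(cur$data[[f]], types[[f]])), feats)
  scaled <- apply_scalers(cur, plan)
  report <- structure(list(
    duplicates_removed = dup$count,
    cells_imputed = imp$count,
    outliers_removed = sum(mask),
    column_transforms = vapply(plan, `[[`, "", "kind"),
    class_counts_before = as.integer(counts_before),
    class_counts_after = as.integer(table(factor(dataset_labels(scaled),
                                                 levels = 0:1)))),
    class = "preprocess_report")
  list(dataset = scaled,
       plan = structure(list(scalers = plan, fallback = fallback,
                             config = cfg), class = "preprocess_plan"),
       report = report)
}

#' Apply a frozen preprocessing plan to unseen rows
#'
#' Missing cells are filled with the training-column mean/mode (labels of
#' unseen rows are never consulted); the frozen scaler plan is then applied
#' verbatim. No rows are dropped or resampled: duplicate/outlier removal and
#' rebalancing are training-time operations.
#' @param ds a [tabular_dataset()] of unseen rows.
#' @param plan a `preprocess_plan` from [preprocess_fit()].
#' @return the transformed dataset.
#' @export
preprocess_apply <- function(ds, plan) {
  stopifnot(inherits(plan, "preprocess_plan"))
  d <- ds$data
  for (f in names(plan$fallback)) {
    miss <- is.na(d[[f]])
    if (any(miss)) d[miss, f] <- plan$fallback[[f]]
  }
  out <- ds
  out$data <- d
  apply_scalers(out, plan$scalers)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  cat(sprintf("  duplicates removed : %d\n", x$duplicates_removed))
  cat(sprintf("  cells imputed      : %d\n", x$cells_imputed))
  cat(sprintf("  outliers removed   : %d\n", x$outliers_removed))
  cat(sprintf("  class counts       : (%s) -> (%s)\n",
              paste(x$class_counts_before, collapse = ", "),
              paste(x$class_counts_after, collapse = ", ")))
  tr <- table(x$column_transforms)
  cat("  column transforms  :",
      paste(sprintf("%s=%d", names(tr), tr), collapse = ", "), "\n")
  invisible(x)
}
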