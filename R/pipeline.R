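.resolve_schema <- function(ref) {
  if (inherits(ref, "dataset_schema")) return(ref)
  if (is.character(ref) && length(ref) == 1) {
    if (ref == "uci") return(uci_schema())
    if (ref == "chd") return(chd_schema())
    return(read_schema(ref))
  }
  abort("schema must be 'uci', 'chd', a file path or a dataset_schema",
        "config_error")
}

.cfg_to_preprocess <- function(x) {
  if (is.null(x)) return(preprocess_config())
  do.call(preprocess_config, x)
}

.cfg_to_base_models <- function(x, seed) {
  if (is.null(x))
    x <- lapply(c("lr", "svm", "xgb", "rf", "dnn", "cnn"),
                function(m) list(model_id = m))
  cfgs <- lapply(x, function(b) {
    b$seed <- b$seed %||% seed
    do.call(base_model_config, b)
  })
  names(cfgs) <- vapply(cfgs, `[[`, "", "model_id")
  cfgs
}

#' Read and validate a run configuration
#'
#' YAML (or JSON) with blocks: `schema` (`"uci"`, `"chd"` or a schema file),
#' `preprocess` ([preprocess_config()] fields), `selection`
#' (`list(x, methods)` or absent to disable), `base_models` (list of
#' [base_model_config()] blocks keyed by `model_id`; absent = all six),
#' `stacking` (`oof_folds`, `combiner`), `evaluation` (`k`, `seed`).
#' @param path config file path.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste("no such config:", path), "config_error")
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  raw$config_path <- path
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @param raw a raw config list.
#' @export
validate_run_config <- function(raw) {
  seed <- raw$evaluation$seed %||% 1L
  cfg <- list(
    schema = .resolve_schema(raw$schema %||% "uci"),
    preprocess = .cfg_to_preprocess(raw$preprocess),
    selection = raw$selection,
    base_models = .cfg_to_base_models(raw$base_models, seed),
    oof_folds = raw$stacking$oof_folds %||% 5L,
    combiner = raw$stacking$combiner %||% "proposed",
    k = raw$evaluation$k %||% 10L,
    seed = as.integer(seed),
    config_path = raw$config_path)
  ok <- cfg$combiner %in% c("proposed", "classical", "majority") ||
    startsWith(cfg$combiner, "single:")
  if (!ok) abort(paste("unrecognized combiner:", cfg$combiner), "config_error")
  if (!is.null(cfg$selection) &&
      cfg$selection$x > length(feature_names(cfg$schema)))
    abort("selection x exceeds feature count", "config_error")
  structure(cfg, class = "run_config")
}

#' Run the full pipeline end to end
#'
#' Fixed stage order: load -> feature selection (on a preprocessed copy of
#' the full data) -> cross-validated evaluation in which preprocessing and
#' all model fitting happen on training partitions only -> deployment fit on
#' all rows. Emits a four-row comparison report (proposed stacking,
#' traditional voting, classical stacking, best single model) plus the
#' configured combiner's CV metrics, all stamped with the config hash and
#' seed; a rerun with the same config and data is byte-identical.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @param data_path CSV of the input dataset.
#' @param out_dir output directory for artifacts (`report.csv`,
#'   `report.json`, `selection.json`, `bundle.rds`).
#' @param table4 also run the four-row framework comparison (default TRUE;
#'   switch off for a quicker single-combiner run).
#' @return invisibly, a list with `report`, `cv`, `selection`, `bundle_path`.
#' @export
run_pipeline <- function(config, data_path, out_dir = "clinstack_run",
                         table4 = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(seed = config$seed,
                config_hash = if (!is.null(config$config_path))
                  unname(tools::md5sum(config$config_path)) else NA_character_)
  message("[load] ", data_path)
  ds <- load_dataset(data_path, config$schema)

  sel <- NULL
  if (!is.null(config$selection)) {
    message("[select] x = ", config$selection$x)
    pp_copy <- preprocess_fit(ds, config$preprocess)$dataset
    methods <- config$selection$methods %||%
      c("pearson", "anova", "rfe", "lasso", "tree")
    sel <- select_features(pp_copy, x = config$selection$x,
                           methods = unlist(methods), seed = config$seed)
    keep <- c(sel$selected, config$schema$label_column)
    sub_schema <- dataset_schema(
      Filter(function(cs) cs$name %in% keep, config$schema$columns),
      config$schema$label_column, config$schema$positive_class)
    ds <- tabular_dataset(ds$data[, schema_column_names(sub_schema),
                                  drop = FALSE], sub_schema)
  }

  message("[evaluate] combiner = ", config$combiner, ", k = ", config$k)
  cv <- cross_validate(ds, config$base_models, combiner = config$combiner,
                       k = config$k, seed = config$seed,
                       preprocess = config$preprocess,
                       oof_folds = config$oof_folds)
  report <- NULL
  if (table4) {
    message("[compare] table4")
    report <- compare_frameworks(ds, config$base_models, mode = "table4",
                                 k = config$k, seed = config$seed,
                                 preprocess = config$preprocess,
                                 oof_folds = config$oof_folds)
    write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  }

  message("[train] deployment fit on all rows")
  pp <- preprocess_fit(ds, config$preprocess)
  sm <- fit_stacked(pp$dataset, config$base_models,
                    oof_folds = config$oof_folds, seed = config$seed,
                    meta_features = if (config$combiner == "classical")
                      "class" else "both")
  bundle <- list(version = 1L, stamp = stamp, schema = ds$schema,
                 preprocess_plan = pp$plan, model = sm, selection = sel)
  bundle_path <- file.path(out_dir, "bundle.rds")
  saveRDS(bundle, bundle_path, version = 2)

  jsonlite::write_json(
    list(stamp = stamp,
         cv = list(combiner = config$combiner, k = config$k,
                   mean_metrics = as.list(cv$mean_metrics)),
         preprocess = unclass(pp$report),
         comparison = report,
         selection = if (!is.null(sel)) list(selected = sel$selected,
                                             intersection = sel$intersection)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  invisible(list(report = report, cv = cv, selection = sel,
                 bundle_path = bundle_path))
}

#' Predict from a saved pipeline bundle
#' @param bundle_path path to a `bundle.rds` written by [run_pipeline()].
#' @param ds a [tabular_dataset()] conforming to the bundle schema.
#' @return `list(class, prob)`.
#' @export
predict_bundle <- function(bundle_path, ds) {
  bundle <- readRDS(bundle_path)
  scaled <- preprocess_apply(ds, bundle$preprocess_plan)
  predict_stacked(bundle$model, scaled)
}
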