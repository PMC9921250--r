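#' Declare a column of a clinical tabular dataset
#'
#' A `column_spec` names a column, gives it a semantic type that downstream
#' stages key on (scaling, one-hot encoding, feature eligibility), and
#' optionally records the admissible range or value set and measurement units.
#'
#' @param name column name (non-empty string).
#' @param type one of `"numeric_continuous"`, `"numeric_ordinal"`, `"binary"`,
#'   `"categorical"`, `"identifier"`.
#' @param range optional numeric `c(min, max)` for numeric columns.
#' @param values optional enumerated value set for ordinal/categorical columns.
#' @param units optional free-text units.
#' @return an object of class `column_spec`.
#' @export
column_spec <- function(name, type, range = NULL, values = NULL, units = NULL) {
  types <- c("numeric_continuous", "numeric_ordinal", "binary", "categorical",
             "identifier")
  stopifnot(is.character(name), nzchar(name), length(name) == 1L)
  type <- match.arg(type, types)
  if (!is.null(range)) {
    stopifnot(is.numeric(range), length(range) == 2L)
    range <- as.numeric(range)
    if (range[1] > range[2]) abort("column range has min > max", "schema_error")
  }
  if (!is.null(values) && is.numeric(values)) values <- as.numeric(values)
  if (type == "binary") values <- c(0, 1)
  structure(list(name = name, type = type, range = range, values = values,
                 units = units), class = "column_spec")
}

#' Declare a dataset schema
#'
#' Orders the columns of a dataset, designates the (binary) label column and
#' its positive class. Identifier-typed columns are never eligible as model
#' features.
#'
#' @param columns list of [column_spec()] objects.
#' @param label_column name of the label column; must be binary-typed.
#' @param positive_class label value counted as positive (default 1).
#' @return an object of class `dataset_schema`.
#' @export
dataset_schema <- function(columns, label_column, positive_class = 1) {
  stopifnot(is.list(columns), length(columns) > 0L)
  nms <- vapply(columns, function(cs) cs$name, character(1))
  if (anyDuplicated(nms)) abort("duplicate column names in schema", "schema_error")
  if (!label_column %in% nms)
    abort(sprintf("label column '%s' not among schema columns", label_column),
          "schema_error")
  lab <- columns[[match(label_column, nms)]]
  if (lab$type != "binary")
    abort("label column must be binary-typed", "schema_error")
  structure(list(columns = columns, label_column = label_column,
                 positive_class = positive_class),
            class = "dataset_schema")
}

#' @export
print.dataset_schema <- function(x, ...) {
  cat(sprintf("<dataset_schema> %d columns, label '%s' (positive = %s)\n",
              length(x$columns), x$label_column, x$positive_class))
  for (cs in x$columns) {
    rng <- if (!is.null(cs$range)) sprintf(" [%g, %g]", cs$range[1], cs$range[2])
           else if (!is.null(cs$values)) paste0(" {", paste(cs$values, collapse = ","), "}")
           else ""
    cat(sprintf("  %-22s %s%s\n", cs$name, cs$type, rng))
  }
  invisible(x)
}

schema_column_names <- function(schema)
  vapply(schema$columns, function(cs) cs$name, character(1))

#' Feature columns of a schema
#'
#' All columns except the label and any identifier-typed columns.
#' @param schema a [dataset_schema()].
#' @return character vector of feature column names.
#' @export
feature_names <- function(schema) {
  nms <- schema_column_names(schema)
  types <- vapply(schema$columns, function(cs) cs$type, character(1))
  nms[nms != schema$label_column & types != "identifier"]
}

schema_col <- function(schema, name)
  schema$columns[[match(name, schema_column_names(schema))]]

#' Reference schema: 14-column UCI heart-disease layout
#'
#' Thirteen clinical features plus a binary `target` label (1 = heart disease
#' present). Ranges reflect the published 1988 sample and are advisory:
#' out-of-range values warn, they do not error.
#' @return a [dataset_schema()].
#' @export
uci_schema <- function() {
  dataset_schema(list(
    column_spec("age",       "numeric_continuous", range = c(29, 77),  units = "years"),
    column_spec("sex",       "binary"),
    column_spec("cp",        "numeric_ordinal", values = 0:3),
    column_spec("chol",      "numeric_continuous", range = c(126, 564), units = "mg/dL"),
    column_spec("restbp",    "numeric_continuous", range = c(94, 564),  units = "mm Hg"),
    column_spec("fbs",       "binary"),
    column_spec("restecg",   "numeric_ordinal", values = 0:2),
    column_spec("heartbeat", "numeric_continuous", range = c(71, 202), units = "bpm"),
    column_spec("exang",     "binary"),
    column_spec("oldpeak",   "numeric_continuous", range = c(0, 6.2)),
    column_spec("slope",     "numeric_ordinal", values = 1:3),
    column_spec("ca",        "numeric_ordinal", values = 0:3),
    column_spec("thal",      "numeric_ordinal", values = 0:3),
    column_spec("target",    "binary")
  ), label_column = "target", positive_class = 1)
}

#' Reference schema: 13-column cardiovascular heart-disease (CHD) layout
#'
#' Twelve features plus the binary `death_event` label from the 299-patient
#' heart-failure cohort layout.
#' @return a [dataset_schema()].
#' @export
chd_schema <- function() {
  dataset_schema(list(
    column_spec("age",                      "numeric_continuous", range = c(40, 95), units = "years"),
    column_spec("sex",                      "binary"),
    column_spec("anemia",                   "binary"),
    column_spec("high_blood_pressure",      "binary"),
    column_spec("creatinine_phosphokinase", "numeric_continuous", range = c(23, 7861), units = "mcg/L"),
    column_spec("diabetes",                 "binary"),
    column_spec("ejection_fraction",        "numeric_continuous", range = c(14, 80), units = "percent"),
    column_spec("platelets",                "numeric_continuous", range = c(25.01, 850), units = "kiloplatelets/mL"),
    column_spec("serum_creatinine",         "numeric_continuous", range = c(0.5, 9.4), units = "mg/dL"),
    column_spec("serum_sodium",             "numeric_continuous", range = c(114, 148), units = "mEq/L"),
    column_spec("smoking",                  "binary"),
    column_spec("time",                     "numeric_continuous", range = c(4, 285), units = "days"),
    column_spec("death_event",              "binary")
  ), label_column = "death_event", positive_class = 1)
}

#' Read or write a schema as YAML/JSON
#'
#' The on-disk dialect mirrors the `column_spec` fields: a `columns` list with
#' `name`/`type`/`range`/`values`/`units`, plus `label_column` and
#' `positive_class`.
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return [dataset_schema()] for `read_schema`; invisibly `path` for
#'   `write_schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path), "config_error")
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  cols <- lapply(raw$columns, function(cc)
    column_spec(cc$name, cc$type, range = unlist(cc$range),
                values = unlist(cc$values), units = cc$units))
  pc <- raw$label_column
  pos <- raw$positive_class %||% 1
  if (is.numeric(pos)) pos <- as.numeric(pos)
  dataset_schema(cols, pc, pos)
}

#' @rdname read_schema
#' @param schema a [dataset_schema()] to serialize.
#' @export
write_schema <- function(schema, path) {
  raw <- list(
    columns = lapply(schema$columns, function(cs)
      Filter(Negate(is.null), list(name = cs$name, type = cs$type,
                                   range = cs$range, values = cs$values,
                                   units = cs$units))),
    label_column = schema$label_column,
    positive_class = schema$positive_class)
  if (grepl("\\.json$", path))
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(raw, path)
  invisible(path)
}
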