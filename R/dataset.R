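#' Construct a tabular dataset bound to a schema
#'
#' Wraps a data frame whose columns match the schema (order and names), with a
#' provenance log of every transformation applied. The label column must only
#' take values in \{0, 1\} (missing labels are not allowed).
#'
#' @param data data frame with one column per schema column.
#' @param schema a [dataset_schema()].
#' @param transform_log list of `(operation, parameters)` records.
#' @return object of class `tabular_dataset`.
#' @export
tabular_dataset <- function(data, schema, transform_log = list()) {
  nms <- schema_column_names(schema)
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols))
    abort(paste("data lacks schema column(s):",
                paste(missing_cols, collapse = ", ")), "schema_mismatch_error")
  if (nrow(data) < 1L) abort("dataset must have at least one row", "schema_error")
  data <- data[, nms, drop = FALSE]
  lab <- data[[schema$label_column]]
  if (anyNA(lab) || !all(lab %in% c(0, 1)))
    abort("label column takes values outside {0, 1}", "label_error")
  rownames(data) <- NULL
  structure(list(data = data, schema = schema, transform_log = transform_log),
            class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset> %d rows x %d columns, label '%s' (%.1f%% positive)\n",
              nrow(x$data), ncol(x$data), x$schema$label_column,
              100 * mean(dataset_labels(x))))
  if (length(x$transform_log))
    cat("  transforms:", paste(vapply(x$transform_log, `[[`, "", "operation"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' Number of rows / labels / feature matrix of a dataset
#' @param ds a [tabular_dataset()].
#' @return `dataset_labels`: integer 0/1 vector; `n_rows`: row count;
#'   `feature_matrix`: numeric matrix of the eligible feature columns
#'   (categorical columns one-hot encoded, provenance in the
#'   `"origin"` attribute).
#' @export
dataset_labels <- function(ds) as.integer(ds$data[[ds$schema$label_column]])

#' @rdname dataset_labels
#' @export
n_rows <- function(ds) nrow(ds$data)

#' @rdname dataset_labels
#' @export
feature_matrix <- function(ds) {
  feats <- feature_names(ds$schema)
  cols <- list(); origin <- character(0)
  for (f in feats) {
    cs <- schema_col(ds$schema, f)
    v <- ds$data[[f]]
    if (cs$type == "categorical") {
      lv <- cs$values %||% sort(unique(v[!is.na(v)]))
      for (l in lv) {             # one-hot at model time; keep original name
        cols[[paste0(f, "=", l)]] <- as.numeric(v == l)
        origin <- c(origin, f)
      }
    } else {
      cols[[f]] <- as.numeric(v)
      origin <- c(origin, f)
    }
  }
  m <- do.call(cbind, cols)
  attr(m, "origin") <- origin
  m
}

log_transform_op <- function(ds, operation, parameters = list()) {
  ds$transform_log <- c(ds$transform_log,
                        list(list(operation = operation, parameters = parameters)))
  ds
}

# values commonly used as missing markers in clinical CSV exports
.missing_markers <- c("", "NA", "?", "nan", "NaN")

#' Load a delimited dataset against a declared schema
#'
#' Reads an RFC-4180 CSV with a header row, binds every schema column to a data
#' column, maps the conventional missing markers (empty cell, `NA`, `?`,
#' `nan`) to explicit missing values, and warns (never drops) on values outside
#' a column's declared range or value set.
#'
#' @param path CSV file path.
#' @param schema a [dataset_schema()].
#' @return a [tabular_dataset()].
#' @export
load_dataset <- function(path, schema) {
  if (!file.exists(path)) abort(paste("no such file:", path), "data_error")
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  na.strings = .missing_markers, strip.white = TRUE)
  nms <- schema_column_names(schema)
  missing_cols <- setdiff(nms, names(raw))
  if (length(missing_cols))
    abort(paste("file lacks schema column(s):",
                paste(missing_cols, collapse = ", ")), "schema_mismatch_error")
  raw <- raw[, nms, drop = FALSE]
  out <- as.data.frame(lapply(nms, function(nm) {
    cs <- schema_col(schema, nm)
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- !is.na(raw[[nm]]) & is.na(v)
    if (any(bad))
      warning(sprintf("column '%s': %d non-numeric value(s) treated as missing",
                      nm, sum(bad)), call. = FALSE)
    v
  }), col.names = nms, check.names = FALSE)
  for (nm in nms) {
    cs <- schema_col(schema, nm)
    v <- out[[nm]]
    oor <- if (!is.null(cs$range)) !is.na(v) & (v < cs$range[1] | v > cs$range[2])
           else if (!is.null(cs$values) && cs$type != "binary") !is.na(v) & !(v %in% cs$values)
           else rep(FALSE, length(v))
    if (any(oor))
      warning(sprintf("column '%s': %d value(s) outside declared range/value set",
                      nm, sum(oor)), call. = FALSE)
  }
  tabular_dataset(out, schema,
                  transform_log = list(list(operation = "load",
                                            parameters = list(path = path))))
}

#' Write a dataset back to CSV
#'
#' Cell values round-trip exactly through [load_dataset()] for numeric data;
#' missing cells are written as empty fields.
#' @param ds a [tabular_dataset()].
#' @param path output CSV path.
#' @export
write_dataset <- function(ds, path) {
  write.csv(ds$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Count missing cells in the feature columns
#' @param ds a [tabular_dataset()].
#' @export
count_missing <- function(ds)
  sum(is.na(ds$data[, feature_names(ds$schema), drop = FALSE]))
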