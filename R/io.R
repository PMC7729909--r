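#' Read a pipeline configuration from JSON or YAML
#'
#' The file holds three blocks: `variables` (a list of
#' `{name, role, domain, na_code}` entries), `hierarchies` (a mapping
#' variable -> `{leaf: [ancestor labels...]}`), and `params`
#' (`k`, `t`, `min_value_count`, `key_threshold`, `seed`). Absent parameters
#' fall back to the defaults of [pipeline_config()] (`k = 11`, `t = 0.5`,
#' `min_value_count = 10`, `key_threshold = 5`).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  if (is.null(raw$variables)) stop("config is missing the 'variables' block", call. = FALSE)
  variables <- lapply(raw$variables, function(v) {
    variable_spec(v$name, v$role, unlist(v$domain), na_code = v$na_code)
  })
  hierarchies <- list()
  if (!is.null(raw$hierarchies)) {
    hierarchies <- lapply(names(raw$hierarchies), function(var) {
      paths <- lapply(raw$hierarchies[[var]], function(p) as.character(unlist(p)))
      hierarchy(var, paths)
    })
  }
  params <- raw$params %||% list()
  pipeline_config(
    variables = variables,
    hierarchies = hierarchies,
    k = params$k %||% 11L,
    t = params$t %||% 0.5,
    min_value_count = params$min_value_count %||% 10L,
    key_threshold = params$key_threshold %||% 5L,
    key_vars = if (!is.null(params$key_vars)) unlist(params$key_vars),
    sensitive_vars = if (!is.null(params$sensitive_vars)) unlist(params$sensitive_vars),
    seed = params$seed
  )
}

#' Write a pipeline configuration to JSON or YAML
#'
#' Inverse of [read_config()]; the format is chosen from the file extension.
#'
#' @param config A [pipeline_config()].
#' @param path Output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  raw <- list(
    variables = lapply(unname(config$variables), function(v) {
      out <- list(name = v$name, role = v$role, domain = as.list(v$domain))
      if (!is.null(v$na_code)) out$na_code <- v$na_code
      out
    }),
    hierarchies = lapply(config$hierarchies, function(h) lapply(h$paths, as.list)),
    params = list(k = config$k, t = config$t,
                  min_value_count = config$min_value_count,
                  key_threshold = config$key_threshold,
                  key_vars = as.list(config$key_vars),
                  sensitive_vars = as.list(config$sensitive_vars),
                  seed = config$seed)
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(raw, path)
  } else {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Read a registry dataset from CSV
#'
#' Cells are read as literal character codes (no value, including the
#' explicit `"NA"` not-applicable code, is ever turned into a missing cell)
#' and validated against the schema: the header must contain exactly the
#' schema's variable names (order-insensitive; columns are reordered to the
#' schema), and every cell must lie in its variable's domain.
#'
#' @param path Path to a UTF-8, comma-separated CSV file with a header row.
#' @param config A [pipeline_config()] supplying the schema.
#' @param id_col Optional name of a column holding stable record ids; when
#'   absent, ids are assigned as the 0-based input row index.
#' @return A tibble with one row per record: a `record_id` integer column
#'   followed by one character column per schema variable.
#' @export
read_dataset <- function(path, config, id_col = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  data <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          na = character(), progress = FALSE)
  expected <- config_vars(config)
  have <- setdiff(names(data), id_col)
  missing_cols <- setdiff(expected, have)
  extra_cols <- setdiff(have, expected)
  if (length(missing_cols)) stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (length(extra_cols)) stop("unknown column(s): ", paste(extra_cols, collapse = ", "), call. = FALSE)
  if (!is.null(id_col)) {
    ids <- as.integer(data[[id_col]])
    if (anyDuplicated(ids) || anyNA(ids)) stop("id column '", id_col, "' must hold unique integers", call. = FALSE)
    data[[id_col]] <- NULL
  } else {
    ids <- seq_len(nrow(data)) - 1L
  }
  data <- dplyr::bind_cols(tibble::tibble(record_id = ids), data[expected])
  validate_dataset(data, config)
  data
}

#' Validate a dataset against a schema
#'
#' Checks that every cell lies in its variable's domain and that record ids
#' are unique. Errors name the offending row, column and value.
#'
#' @param data A dataset tibble (as returned by [read_dataset()] or the
#'   simulators).
#' @param config A [pipeline_config()].
#' @return `data`, invisibly.
#' @export
validate_dataset <- function(data, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!"record_id" %in% names(data)) stop("dataset is missing the 'record_id' column", call. = FALSE)
  if (anyDuplicated(data$record_id)) stop("record ids are not unique", call. = FALSE)
  for (v in config_vars(config)) {
    if (!v %in% names(data)) stop("missing column(s): ", v, call. = FALSE)
    bad <- which(!data[[v]] %in% config_domain(config, v))
    if (length(bad)) {
      i <- bad[1L]
      stop("out-of-domain value in row ", i, ", column '", v, "': '",
           data[[v]][i], "' (", length(bad), " offending cell(s) in this column)",
           call. = FALSE)
    }
  }
  invisible(data)
}

#' Write a registry dataset to CSV
#'
#' Writes values as literal codes in schema column order; the `record_id`
#' bookkeeping column is dropped so the file matches the public release
#' format. A header-only file is written for an empty dataset.
#'
#' @param data A dataset tibble.
#' @param path Output CSV path.
#' @param keep_id Keep `record_id` as the first column (useful for audits).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, keep_id = FALSE) {
  out <- if (keep_id) data else dplyr::select(data, -dplyr::any_of("record_id"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
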