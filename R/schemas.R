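#' Table schemas used by the readers and the validator
#'
#' The four input tables (`dietary_records`, `food_table`, `surveys`, `sites`)
#' are plain UTF-8 CSV files with a mandatory header row and the string `NA`
#' for missing values. Their column types, allowed category strings and
#' numeric ranges are declared in a machine-readable JSON file shipped with
#' the package; this function returns the parsed declaration.
#'
#' @return Named list, one entry per table, each with a `file` name and a
#'   `columns` list (type, required, allowed values, min/max).
#' @export
cohort_schemas <- function() {
  path <- system.file("extdata", "schemas.json", package = "dietaging")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

schema_col_types <- function(schema) {
  mk <- function(col) {
    switch(col$type,
           character = readr::col_character(),
           integer   = readr::col_integer(),
           double    = readr::col_double(),
           abort(sprintf("Unknown schema type `%s`.", col$type)))
  }
  do.call(readr::cols, lapply(schema$columns, mk))
}

# Validate one parsed table against its schema declaration. Returns the data
# invisibly; aborts with a named schema or row-level error otherwise.
check_schema <- function(data, schema, table_name) {
  declared <- names(schema$columns)
  missing_cols <- setdiff(declared, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Schema error in `%s`: missing column(s) %s.",
                  table_name, paste0("`", missing_cols, "`", collapse = ", ")))
  }
  for (col in declared) {
    decl <- schema$columns[[col]]
    v <- data[[col]]
    if (isTRUE(decl$required) && anyNA(v)) {
      rows <- which(is.na(v))
      abort(sprintf(
        "Schema error in `%s`: column `%s` must not be missing (first bad row: %d).",
        table_name, col, rows[1]))
    }
    if (!is.null(decl$allowed)) {
      allowed <- unlist(decl$allowed)
      bad <- !is.na(v) & !(v %in% allowed)
      if (any(bad)) {
        abort(sprintf(
          "Schema error in `%s`: column `%s` has value `%s` outside {%s} (row %d).",
          table_name, col, v[which(bad)[1]], paste(allowed, collapse = ", "),
          which(bad)[1]))
      }
    }
    if (!is.null(decl$min)) {
      bad <- !is.na(v) & v < decl$min
      if (any(bad)) {
        abort(sprintf("Schema error in `%s`: column `%s` below %s (row %d).",
                      table_name, col, decl$min, which(bad)[1]))
      }
    }
    if (!is.null(decl$max)) {
      bad <- !is.na(v) & v > decl$max
      if (any(bad)) {
        abort(sprintf("Schema error in `%s`: column `%s` above %s (row %d).",
                      table_name, col, decl$max, which(bad)[1]))
      }
    }
  }
  invisible(data)
}

read_one_table <- function(path, table_name) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  schema <- cohort_schemas()[[table_name]]
  # readr's own parse warnings are redundant here: problems() and the schema
  # check below turn them into named errors.
  data <- tryCatch(
    suppressWarnings(
      readr::read_csv(path, col_types = schema_col_types(schema),
                      na = "NA", progress = FALSE)),
    error = function(e) abort(sprintf("Cannot parse %s: %s", path, conditionMessage(e)))
  )
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(sprintf("Parse error in %s at line %d: expected %s, got `%s`.",
                  path, probs$row[1], probs$expected[1], probs$actual[1]))
  }
  check_schema(data, schema, table_name)
  data
}

#' Read the dietary-records table
#'
#' One row per food item eaten by one participant on one 24-hour recall day.
#'
#' @param path Path to `dietary_records.csv`.
#' @return A tibble with columns `participant_id`, `wave`, `day`, `food_id`,
#'   `amount` (grams).
#' @export
read_dietary_records <- function(path) read_one_table(path, "dietary_records")

#' Read the food-composition table
#'
#' @param path Path to `food_table.csv`.
#' @return A tibble with `food_id`, `energy_density` (kcal per 100 g) and
#'   `food_group` (one of the ten guideline groups).
#' @export
read_food_table <- function(path) read_one_table(path, "food_table")

#' Read the participant survey table
#'
#' @param path Path to `surveys.csv`.
#' @return A tibble with baseline covariates and outcome-wave questionnaire
#'   responses, one row per participant.
#' @export
read_surveys <- function(path) read_one_table(path, "surveys")

#' Read the survey-site table
#'
#' @param path Path to `sites.csv`.
#' @return A tibble with `site_id` and `region`.
#' @export
read_sites <- function(path) read_one_table(path, "sites")
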