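#' Read and validate a prefecture workforce panel
#'
#' A panel is a long-format table with one row per prefecture and year and
#' columns `prefecture` (identifier), `year` (integer), `stock` (practicing
#' physicians counted at that survey year; may be `NA` in licensing-only
#' years) and `new_licensed` (newly licensed physicians attributed to the
#' prefecture that year; may be `NA` in stock-only survey years). Counts are
#' kept as doubles: downstream proportional allocation produces fractional
#' counts and exact conservation of totals is the property the method rests
#' on, so nothing is ever rounded to integers.
#'
#' @param path Path to a UTF-8 CSV with header
#'   `prefecture,year,stock,new_licensed`.
#' @param baseline_year,final_year Optional window bounds. Rows with years
#'   outside `[baseline_year, final_year]` are dropped with a warning that
#'   reports how many were rejected.
#' @return A validated tibble with columns `prefecture` (character), `year`
#'   (integer), `stock` (double), `new_licensed` (double), sorted by
#'   prefecture then year.
#' @export
#' @examples
#' p <- tibble::tibble(
#'   prefecture = rep(c("A", "B"), each = 2),
#'   year = rep(c(2000L, 2010L), 2),
#'   stock = c(100, 150, 200, 210),
#'   new_licensed = c(10, 12, 5, 6)
#' )
#' tf <- tempfile(fileext = ".csv")
#' write_panel(p, tf)
#' read_panel(tf)
read_panel <- function(path, baseline_year = NULL, final_year = NULL) {
  raw <- read_physmig_csv(path, c("prefecture", "year", "stock", "new_licensed"))
  panel <- tibble(
    prefecture = as.character(raw$prefecture),
    year = coerce_numeric(raw$year, "year", path),
    stock = coerce_numeric(raw$stock, "stock", path),
    new_licensed = coerce_numeric(raw$new_licensed, "new_licensed", path)
  )
  if (!is.null(baseline_year) || !is.null(final_year)) {
    lo <- baseline_year %||% -Inf
    hi <- final_year %||% Inf
    keep <- panel$year >= lo & panel$year <= hi
    if (any(!keep)) {
      warn(sprintf(
        "read_panel: rejected %d row(s) with years outside [%s, %s]",
        sum(!keep), format(lo), format(hi)
      ))
      panel <- panel[keep, , drop = FALSE]
    }
  }
  panel$year <- as.integer(panel$year)
  validate_panel(panel)
}

#' Write a prefecture panel to CSV
#'
#' Output is deterministic: rows sorted by `prefecture` (lexicographic) then
#' `year` ascending, UTF-8, `.` decimal separator. [read_panel()] inverts it.
#'
#' @param panel A panel tibble as returned by [read_panel()] or
#'   [simulate_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  write_physmig_csv(panel, path)
}

#' Validate a panel table
#'
#' Checks the column contract of the panel format: required columns present,
#' no duplicated (prefecture, year) pair, all counts non-negative. Malformed
#' input raises a typed condition (`physmig_error_schema`,
#' `physmig_error_integrity` or `physmig_error_validation`); nothing is
#' silently coerced or dropped.
#'
#' @param panel A data frame.
#' @return The panel as a tibble, sorted by prefecture then year.
#' @export
validate_panel <- function(panel) {
  require_columns(panel, c("prefecture", "year", "stock", "new_licensed"), "panel")
  panel <- as_tibble(panel)
  dup <- duplicated(panel[c("prefecture", "year")])
  if (any(dup)) {
    bad <- panel[dup, c("prefecture", "year")]
    stop_physmig(
      sprintf(
        "duplicate (prefecture, year) rows: %s",
        paste(sprintf("(%s, %s)", bad$prefecture, bad$year), collapse = ", ")
      ),
      "integrity"
    )
  }
  for (col in c("stock", "new_licensed")) {
    v <- panel[[col]]
    if (any(v < 0, na.rm = TRUE)) {
      stop_physmig(sprintf("negative values in column '%s'", col), "validation")
    }
  }
  if (any(is.na(panel$year)) || any(panel$year != trunc(panel$year))) {
    stop_physmig("column 'year' must contain whole numbers", "validation")
  }
  dplyr::arrange(panel, .data$prefecture, .data$year)
}

#' Read and validate a prefecture covariate table
#'
#' One row per prefecture with the eight socio-demographic covariates used by
#' the association analysis: `practicing_ppr` (practicing physicians per
#' 100,000 population), `new_licensed_ppr` (annual newly licensed physicians
#' per 100,000), `physician_mean_age` (years), `female_ratio` (proportion of
#' female physicians, in \[0,1\]), `pop_density` (persons per km^2 of
#' inhabitable land), `unemployment` (proportion), `aged_ratio` (proportion
#' aged 65+) and `income` (average income of the general population, currency
#' units).
#'
#' @param path Path to a CSV with header
#'   `prefecture,practicing_ppr,new_licensed_ppr,physician_mean_age,female_ratio,pop_density,unemployment,aged_ratio,income`.
#' @return A validated tibble sorted by prefecture.
#' @export
read_covariates <- function(path) {
  raw <- read_physmig_csv(path, covariate_schema())
  cov <- as_tibble(raw)
  cov$prefecture <- as.character(cov$prefecture)
  for (col in setdiff(covariate_schema(), "prefecture")) {
    cov[[col]] <- coerce_numeric(cov[[col]], col, path)
  }
  validate_covariates(cov)
}

#' Write a covariate table to CSV
#'
#' @param covariates A covariate tibble (see [read_covariates()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  covariates <- validate_covariates(covariates)
  write_physmig_csv(covariates, path)
}

#' Validate a covariate table
#'
#' @param covariates A data frame with the covariate schema of
#'   [read_covariates()].
#' @return The covariates as a tibble sorted by prefecture.
#' @export
validate_covariates <- function(covariates) {
  require_columns(covariates, covariate_schema(), "covariates")
  covariates <- as_tibble(covariates)
  if (anyDuplicated(covariates$prefecture)) {
    stop_physmig("duplicate prefecture rows in covariate table", "integrity")
  }
  for (col in c("female_ratio", "unemployment", "aged_ratio")) {
    v <- covariates[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop_physmig(sprintf("column '%s' must lie in [0, 1]", col), "validation")
    }
  }
  for (col in c("practicing_ppr", "new_licensed_ppr", "physician_mean_age",
                "pop_density", "income")) {
    if (any(covariates[[col]] < 0, na.rm = TRUE)) {
      stop_physmig(sprintf("column '%s' must be non-negative", col), "validation")
    }
  }
  dplyr::arrange(covariates, .data$prefecture)
}

covariate_schema <- function() {
  c("prefecture", "practicing_ppr", "new_licensed_ppr", "physician_mean_age",
    "female_ratio", "pop_density", "unemployment", "aged_ratio", "income")
}

covariate_names <- function() setdiff(covariate_schema(), "prefecture")

read_physmig_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop_physmig(sprintf("file not found: %s", path), "io")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  require_columns(raw, required, path)
  raw
}

write_physmig_csv <- function(x, path) {
  x <- dplyr::arrange(x, dplyr::across(dplyr::any_of(c("prefecture", "year"))))
  tryCatch(
    readr::write_csv(x, path, progress = FALSE),
    error = function(e) stop_physmig(sprintf("cannot write '%s': %s", path, conditionMessage(e)), "io")
  )
  invisible(path)
}

require_columns <- function(x, required, what) {
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop_physmig(
      sprintf("%s: missing required column(s): %s", what, paste(missing, collapse = ", ")),
      "schema"
    )
  }
  invisible(x)
}

coerce_numeric <- function(v, col, what) {
  if (is.numeric(v)) return(as.double(v))
  out <- suppressWarnings(as.double(v))
  bad <- !is.na(v) & v != "" & is.na(out)
  if (any(bad)) {
    stop_physmig(
      sprintf("%s: column '%s' has non-numeric value(s): %s",
              what, col, paste(unique(v[bad]), collapse = ", ")),
      "validation"
    )
  }
  out
}
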