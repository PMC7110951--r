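#' Read a year-indexed series from CSV
#'
#' Reads and validates one of the three CSV dialects the package uses:
#' census (`year,count[,season]`), climate (`year,winter_precip_mm`) and
#' wardens (`year,wardens`). A header row is required; files are UTF-8.
#' Schema mismatches, non-numeric cells, duplicate years and negative
#' values are rejected with distinct messages naming the offending row or
#' year.
#'
#' @param path Path to the CSV file.
#' @param kind One of `"census"`, `"climate"`, `"wardens"`.
#' @return A validated tibble: census (`year`, `count`, optional
#'   `season`), climate (`year`, `precip`) or wardens (`year`,
#'   `wardens`).
#' @export
read_series <- function(path, kind = c("census", "climate", "wardens")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path),
                 class = "ibexdyn_error_io")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- switch(kind,
    census = c("year", "count"),
    climate = c("year", "winter_precip_mm"),
    wardens = c("year", "wardens")
  )
  if (!all(required %in% names(raw))) {
    rlang::abort(
      sprintf("schema mismatch for kind \"%s\": expected columns %s, found %s.",
              kind, paste(required, collapse = ","),
              paste(names(raw), collapse = ",")),
      class = "ibexdyn_error_schema"
    )
  }
  year <- parse_numeric_column(raw$year, "year", path)
  value_col <- required[2]
  value <- parse_numeric_column(raw[[value_col]], value_col, path)
  if (anyDuplicated(year)) {
    rlang::abort(sprintf("duplicate year %d in %s.",
                         as.integer(year[duplicated(year)][1]), path),
                 class = "ibexdyn_error_duplicate_year")
  }
  if (any(value < 0)) {
    row <- which(value < 0)[1]
    rlang::abort(sprintf("negative %s in row %d of %s.", value_col, row, path),
                 class = "ibexdyn_error_value")
  }
  switch(kind,
    census = {
      season <- if ("season" %in% names(raw)) raw$season else NULL
      population_series(year, value, season)
    },
    climate = climate_series(year, value),
    wardens = dplyr::arrange(
      tibble::tibble(year = as.integer(year), wardens = value), .data$year
    )
  )
}

parse_numeric_column <- function(x, name, path) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    row <- which(is.na(out))[1]
    rlang::abort(
      sprintf("non-numeric `%s` value %s in row %d of %s.",
              name, deparse(x[row]), row, path),
      class = "ibexdyn_error_parse"
    )
  }
  out
}

#' Write a forecast or validation report to CSV
#'
#' Serialises an [simulate_ensemble()] forecast or a
#' [validate_out_of_sample()] report to the package's CSV dialect.
#' Forecast rows carry both the raw (continuous) and rounded summaries,
#' plus the ensemble configuration (`n_real`, `band_level`, `seed`) so
#' the file is self-describing; the round trip through [readr::read_csv()]
#' preserves values to better than 1e-9. An empty report yields a
#' header-only file.
#'
#' @param x An `ibex_forecast` or `ibex_validation` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  UseMethod("write_report")
}

#' @export
write_report.ibex_forecast <- function(x, path) {
  df <- tidy.ibex_forecast(x) |>
    dplyr::mutate(
      mean_rounded = round(.data$mean),
      band_lower_rounded = round(.data$band_lower),
      band_upper_rounded = round(.data$band_upper),
      n_real = x$n_real,
      band_level = x$band_level,
      seed = x$seed
    )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @export
write_report.ibex_validation <- function(x, path) {
  df <- x$table |>
    dplyr::mutate(
      observed_rounded = round(.data$observed),
      first_exit = !is.na(x$first_exit_year) & .data$year == x$first_exit_year
    )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a run-metadata echo
#'
#' Records the configuration a run actually used — variant, windows, seed,
#' quantile method, row counts, package version — as a small JSON file, so
#' any output directory is self-describing and reproducible.
#'
#' @param config A named list of scalar settings.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path) {
  config$ibexdyn_version <- as.character(utils::packageVersion("ibexdyn"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# census/climate/warden writers sharing read_series()'s dialects
write_series <- function(df, path, kind = c("census", "climate", "wardens")) {
  kind <- match.arg(kind)
  out <- switch(kind,
    census = dplyr::select(df, dplyr::any_of(c("year", "count", "season"))),
    climate = tibble::tibble(year = df$year, winter_precip_mm = df$precip),
    wardens = dplyr::select(df, "year", "wardens")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
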