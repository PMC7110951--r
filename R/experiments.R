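#' Windowed fit-forecast-validate experiment
#'
#' The core protocol: fit the model on the census up to `fit_end_year`,
#' launch an ensemble forecast from the last observed count of the fit
#' window, and validate it against every later observation. With
#' `fit_end_year` at the end of the series the forecast and report are
#' empty (no validated years), which is returned gracefully rather than
#' as an error.
#'
#' @param pop Census tibble (`year`, `count`).
#' @param clim Climate tibble (`year`, `precip`).
#' @param variant `"D1"` or `"D2"`.
#' @param fit_end_year Last census year included in the fit window.
#' @param n_real Ensemble size; default 1000.
#' @param seed Integer seed for the ensemble noise.
#' @param band_level Band level; default 0.90.
#'
#' @return An object of class `ibex_experiment`: list with `fit`
#'   (`ibex_fit`), `forecast` (`ibex_forecast`), `validation`
#'   (`ibex_validation`), `fit_window` and `seed`.
#' @export
run_windowed <- function(pop, clim, variant = "D2", fit_end_year,
                         n_real = 1000, seed, band_level = 0.90) {
  pop <- validate_population(pop)
  clim <- validate_climate(clim)
  fit_end_year <- as.integer(fit_end_year)
  if (!fit_end_year %in% pop$year) {
    rlang::abort("`fit_end_year` must be a census year.",
                 class = "ibexdyn_error_value")
  }
  fit_window <- c(min(pop$year), fit_end_year)
  fit <- fit_model(pop, clim, variant = variant, train_window = fit_window)

  launch <- dplyr::filter(pop, .data$year <= fit_end_year)
  n_start <- launch$count[which.max(launch$year)]
  end_year <- min(max(pop$year), max(clim$year))

  forecast <- simulate_ensemble(
    fit, n_start = n_start, start_year = fit_end_year, clim = clim,
    n_real = n_real, seed = seed, band_level = band_level,
    end_year = max(end_year, fit_end_year)
  )
  validation <- if (length(intersect(forecast$years, pop$year)) > 0) {
    validate_out_of_sample(forecast, pop)
  } else {
    new_validation(tibble::tibble(
      year = integer(), observed = double(),
      band_lower = double(), band_upper = double(), inside = logical()
    ))
  }
  structure(
    list(fit = fit, forecast = forecast, validation = validation,
         fit_window = fit_window, seed = as.integer(seed)),
    class = "ibex_experiment"
  )
}

#' @export
print.ibex_experiment <- function(x, ...) {
  cat(sprintf("<ibex_experiment> fit %d-%d (%s), %d forecast year(s)\n",
              x$fit_window[1], x$fit_window[2], x$fit$variant,
              length(x$forecast$years)))
  print(glance.ibex_experiment(x))
  invisible(x)
}

#' One-row summary of a windowed experiment
#'
#' @param x An `ibex_experiment` object.
#' @param ... Unused.
#' @return A one-row tibble: variant, fit window, coefficients, sigma,
#'   forecast trend sign, coverage and first exit year.
#' @method glance ibex_experiment
#' @export
glance.ibex_experiment <- function(x, ...) {
  trend <- if (length(x$forecast$years) >= 2) {
    m <- x$forecast$mean_traj
    sign(m[length(m)] - m[1])
  } else {
    NA_real_
  }
  tibble::tibble(
    variant = x$fit$variant,
    train_start = x$fit_window[1],
    train_end = x$fit_window[2],
    a = x$fit$coef[["a"]], b = x$fit$coef[["b"]],
    c = x$fit$coef[["c"]], d = x$fit$coef[["d"]],
    sigma = x$fit$sigma,
    forecast_trend = trend,
    coverage = x$validation$coverage,
    first_exit_year = as.integer(x$validation$first_exit_year)
  )
}

second_column <- function(df, arg) {
  num <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "year")
  if (!"year" %in% names(df) || length(num) == 0) {
    rlang::abort(
      sprintf("`%s` must have a `year` column and one numeric value column.", arg),
      class = "ibexdyn_error_schema"
    )
  }
  num[1]
}

#' Squared correlation between two annual series
#'
#' Used to validate one climate record as a proxy for another (e.g. the
#' station-average winter precipitation against snow depth at a reference
#' station): the squared Pearson correlation of the paired annual values
#' over an optional year window.
#'
#' @param series_a,series_b Tibbles with a `year` column and one numeric
#'   value column each.
#' @param window Optional length-2 year window `(first, last)`.
#'
#' @return A one-row tibble: `r_squared`, `n_pairs`, `window_start`,
#'   `window_end`.
#' @export
proxy_correlation <- function(series_a, series_b, window = NULL) {
  va <- second_column(series_a, "series_a")
  vb <- second_column(series_b, "series_b")
  a <- tibble::tibble(year = series_a$year, value_a = series_a[[va]])
  b <- tibble::tibble(year = series_b$year, value_b = series_b[[vb]])
  df <- dplyr::inner_join(a, b, by = "year")
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$year >= window[1], .data$year <= window[2])
  }
  if (nrow(df) < 3) {
    rlang::abort(
      sprintf("only %d overlapping year(s); at least 3 pairs are required.",
              nrow(df)),
      class = "ibexdyn_error_too_few_obs"
    )
  }
  tibble::tibble(
    r_squared = stats::cor(df$value_a, df$value_b)^2,
    n_pairs = nrow(df),
    window_start = min(df$year),
    window_end = max(df$year)
  )
}

#' Average precipitation across meteorological stations
#'
#' Per-year arithmetic mean over the stations reporting that year; the
#' output covers the union of the stations' years and records how many
#' stations contributed to each value.
#'
#' @param stations A list of climate tibbles (`year`, `precip`).
#' @return A climate tibble `year`, `precip`, `n_stations`.
#' @export
station_average <- function(stations) {
  if (!is.list(stations) || length(stations) == 0 || is.data.frame(stations)) {
    rlang::abort("`stations` must be a non-empty list of climate series.",
                 class = "ibexdyn_error_value")
  }
  stations <- lapply(seq_along(stations), function(i) {
    validate_climate(stations[[i]], arg = sprintf("stations[[%d]]", i))
  })
  dplyr::bind_rows(stations) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(precip = mean(.data$precip),
                     n_stations = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$year)
}

#' Lagged correlation between a driver series and population changes
#'
#' Correlates year-over-year changes in a driver (e.g. the warden
#' headcount) with year-over-year changes in the census, after shifting
#' the driver forward by `lag` years — a driver change in year `y` is
#' paired with the population change in year `y + lag`. First differences
#' are the default because the comparison concerns lagged *changes*;
#' `use_changes = FALSE` correlates levels instead. Pearson correlation by
#' default; `method = "spearman"` is available as a robustness switch.
#'
#' @param driver Tibble with `year` and one numeric value column.
#' @param response Census tibble (`year`, `count`).
#' @param lag Non-negative integer lag in years; default 1.
#' @param use_changes Correlate first differences (default) or levels.
#' @param method `"pearson"` (default) or `"spearman"`.
#'
#' @return A one-row tibble: `correlation`, `lag`, `n_pairs`.
#' @export
lagged_correlation <- function(driver, response, lag = 1,
                               use_changes = TRUE, method = "pearson") {
  vd <- second_column(driver, "driver")
  response <- validate_population(response)
  d <- tibble::tibble(year = as.integer(driver$year), value = driver[[vd]])
  r <- tibble::tibble(year = response$year, value = response$count)
  if (use_changes) {
    d <- annual_changes(d)
    r <- annual_changes(r)
  }
  d$year <- d$year + as.integer(lag)
  df <- dplyr::inner_join(d, r, by = "year", suffix = c("_driver", "_response"))
  if (nrow(df) < 3) {
    rlang::abort(
      sprintf("only %d pair(s) after applying lag %d; at least 3 are required.",
              nrow(df), lag),
      class = "ibexdyn_error_too_few_obs"
    )
  }
  tibble::tibble(
    correlation = stats::cor(df$value_driver, df$value_response,
                             method = method),
    lag = as.integer(lag),
    n_pairs = nrow(df)
  )
}

# first differences over consecutive years only (gaps are skipped)
annual_changes <- function(df) {
  df <- dplyr::arrange(df, .data$year)
  n <- nrow(df)
  if (n < 2) return(tibble::tibble(year = integer(), value = double()))
  keep <- df$year[-1] - df$year[-n] == 1L
  tibble::tibble(
    year = df$year[-1][keep],
    value = (df$value[-1] - df$value[-n])[keep]
  )
}

#' Consistency of spring and autumn censuses
#'
#' Pearson correlation between paired spring and autumn counts over their
#' common years. A strong correlation supports using either season's
#' counts in the growth model.
#'
#' @param spring,autumn Census tibbles (`year`, `count`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `correlation`, `n_pairs`.
#' @export
seasonal_consistency <- function(spring, autumn, method = "pearson") {
  spring <- validate_population(spring)
  autumn <- validate_population(autumn)
  df <- dplyr::inner_join(spring, autumn, by = "year",
                          suffix = c("_spring", "_autumn"))
  if (nrow(df) < 3) {
    rlang::abort(
      sprintf("only %d common year(s); at least 3 are required.", nrow(df)),
      class = "ibexdyn_error_too_few_obs"
    )
  }
  tibble::tibble(
    correlation = stats::cor(df$count_spring, df$count_autumn, method = method),
    n_pairs = nrow(df)
  )
}
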