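#' Build a validated census series
#'
#' A census series is a tibble with one row per surveyed year: an integer
#' `year` and a non-negative `count` of animals, plus an optional `season`
#' label (`"spring"` or `"autumn"`). Missing survey years are absent rows,
#' never zeros; a zero count marks extinction.
#'
#' @param year Integer vector of calendar years, strictly increasing.
#' @param count Non-negative numeric vector of animals counted.
#' @param season Optional character vector, `"spring"` or `"autumn"`.
#'
#' @return A tibble with columns `year`, `count` and, when supplied,
#'   `season`.
#' @export
#' @examples
#' population_series(1922:1925, c(2370, 2600, 2850, 3100))
population_series <- function(year, count, season = NULL) {
  out <- tibble::tibble(year = as.integer(year), count = as.numeric(count))
  if (!is.null(season)) {
    out$season <- as.character(season)
  }
  validate_population(out)
}

#' Build a validated winter-climate series
#'
#' Winter is November through April; each total is attributed to the
#' calendar year the winter ends in. Precipitation totals act as a proxy
#' for snow depth when forcing the population model.
#'
#' @param year Integer vector of calendar years (the year each winter ends
#'   in), strictly increasing.
#' @param precip Non-negative numeric vector of total Nov-Apr precipitation
#'   in mm.
#'
#' @return A tibble with columns `year` and `precip`.
#' @export
#' @examples
#' climate_series(1923:1926, c(410, 520, 380, 455))
climate_series <- function(year, precip) {
  validate_climate(tibble::tibble(year = as.integer(year),
                                  precip = as.numeric(precip)))
}

validate_population <- function(pop, arg = "pop") {
  if (!is.data.frame(pop) || !all(c("year", "count") %in% names(pop))) {
    rlang::abort(
      sprintf("`%s` must be a data frame with columns `year` and `count`.", arg),
      class = "ibexdyn_error_schema"
    )
  }
  check_years(pop$year, arg)
  if (anyNA(pop$count) || any(pop$count < 0)) {
    rlang::abort(
      sprintf("`%s$count` must be non-negative and non-missing.", arg),
      class = "ibexdyn_error_value"
    )
  }
  if ("season" %in% names(pop) &&
      !all(pop$season %in% c("spring", "autumn", NA_character_))) {
    rlang::abort("`season` labels must be \"spring\" or \"autumn\".",
                 class = "ibexdyn_error_value")
  }
  dplyr::arrange(tibble::as_tibble(pop), .data$year)
}

validate_climate <- function(clim, arg = "clim") {
  if (!is.data.frame(clim) || !all(c("year", "precip") %in% names(clim))) {
    rlang::abort(
      sprintf("`%s` must be a data frame with columns `year` and `precip`.", arg),
      class = "ibexdyn_error_schema"
    )
  }
  check_years(clim$year, arg)
  if (anyNA(clim$precip) || any(clim$precip < 0)) {
    rlang::abort(
      sprintf("`%s$precip` must be non-negative and non-missing.", arg),
      class = "ibexdyn_error_value"
    )
  }
  dplyr::arrange(tibble::as_tibble(clim), .data$year)
}

check_years <- function(year, arg) {
  if (anyNA(year)) {
    rlang::abort(sprintf("`%s$year` contains missing values.", arg),
                 class = "ibexdyn_error_value")
  }
  if (anyDuplicated(year)) {
    dup <- year[duplicated(year)][1]
    rlang::abort(sprintf("duplicate year %d in `%s`.", dup, arg),
                 class = "ibexdyn_error_duplicate_year")
  }
  invisible(year)
}

#' Annual log growth rates of a census series
#'
#' Computes `r_t = ln(N_t / N_{t-1})` for every pair of consecutive survey
#' years, attributing the rate to the later year `t` (the winter ending in
#' year `t` forces the growth from the count in year `t - 1` to the count
#' in year `t`). Pairs spanning a gap in the series are skipped, never
#' interpolated.
#'
#' @param pop Census tibble with columns `year` and `count`
#'   (see [population_series()]).
#'
#' @return A tibble with columns `year` (the later year of each pair),
#'   `r` (the log growth rate) and `n_prev` (the count in the earlier
#'   year). Zero rows when no consecutive pair exists.
#' @export
#' @examples
#' growth_rates(population_series(1930:1932, c(100, 110, 99)))
growth_rates <- function(pop) {
  pop <- validate_population(pop)
  n <- nrow(pop)
  if (n < 2) {
    return(tibble::tibble(year = integer(), r = double(), n_prev = double()))
  }
  prev <- pop[-n, ]
  cur <- pop[-1, ]
  used <- cur$year - prev$year == 1L
  if (any(used & (prev$count == 0 | cur$count == 0))) {
    bad <- cur$year[used & (prev$count == 0 | cur$count == 0)][1]
    rlang::abort(
      sprintf(paste0("zero count in the pair ending %d: the log growth rate ",
                     "is undefined (extinction must be handled upstream)."), bad),
      class = "ibexdyn_error_zero_count"
    )
  }
  tibble::tibble(
    year = cur$year[used],
    r = log(cur$count[used] / prev$count[used]),
    n_prev = prev$count[used]
  )
}
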