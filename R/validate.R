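#' Validate out-of-sample forecasts against observed counts
#'
#' Flags, for every forecast year with an observation, whether the
#' observed count lies inside the closed empirical band
#' `[band_lower, band_upper]`. Ties at the band edge count as inside, so a
#' zero-noise model never alarms on its own mean. Unobserved forecast
#' years are simply skipped.
#'
#' @param forecast An `ibex_forecast` object.
#' @param observed Census tibble (`year`, `count`).
#'
#' @return An object of class `ibex_validation`: list with `table`
#'   (tibble `year`, `observed`, `band_lower`, `band_upper`, `inside`),
#'   `coverage` (fraction of validated years inside the band) and
#'   `first_exit_year` (earliest outside year, `NA` when none).
#' @seealso [first_band_exit()]
#' @export
validate_out_of_sample <- function(forecast, observed) {
  stopifnot(inherits(forecast, "ibex_forecast"))
  observed <- validate_population(observed)
  common <- intersect(forecast$years, observed$year)
  if (length(common) == 0) {
    rlang::abort("observed years do not intersect the forecast years.",
                 class = "ibexdyn_error_no_overlap")
  }
  idx_f <- match(common, forecast$years)
  idx_o <- match(common, observed$year)
  obs <- observed$count[idx_o]
  lower <- forecast$band_lower[idx_f]
  upper <- forecast$band_upper[idx_f]
  tab <- tibble::tibble(
    year = as.integer(common),
    observed = obs,
    band_lower = lower,
    band_upper = upper,
    inside = obs >= lower & obs <= upper
  )
  new_validation(tab)
}

new_validation <- function(tab) {
  outside <- tab$year[!tab$inside]
  structure(
    list(
      table = tab,
      coverage = if (nrow(tab) > 0) mean(tab$inside) else NA_real_,
      first_exit_year = if (length(outside) > 0) min(outside) else NA_integer_
    ),
    class = "ibex_validation"
  )
}

#' First year observations leave the prediction band
#'
#' The "alarm bell" of the protocol: the earliest validated year whose
#' observed count falls outside the ensemble band. From that year onwards
#' causes other than density and climate must be considered.
#'
#' @param report An `ibex_validation` object.
#' @return The first exit year as an integer, or `NA` when observations
#'   never leave the band.
#' @export
first_band_exit <- function(report) {
  stopifnot(inherits(report, "ibex_validation"))
  as.integer(report$first_exit_year)
}

#' @export
print.ibex_validation <- function(x, ...) {
  cat(sprintf("<ibex_validation> %d year(s), coverage %.2f, first exit: %s\n",
              nrow(x$table), x$coverage,
              if (is.na(x$first_exit_year)) "none" else x$first_exit_year))
  print(x$table)
  invisible(x)
}

#' Tidy a validation report
#'
#' @param x An `ibex_validation` object.
#' @param ... Unused.
#' @return The per-year validation tibble (`year`, `observed`,
#'   `band_lower`, `band_upper`, `inside`).
#' @method tidy ibex_validation
#' @export
tidy.ibex_validation <- function(x, ...) {
  x$table
}

#' One-row summary of a validation report
#'
#' @param x An `ibex_validation` object.
#' @param ... Unused.
#' @return A one-row tibble with `n_years`, `coverage`, `first_exit_year`.
#' @method glance ibex_validation
#' @export
glance.ibex_validation <- function(x, ...) {
  tibble::tibble(
    n_years = nrow(x$table),
    coverage = x$coverage,
    first_exit_year = as.integer(x$first_exit_year)
  )
}

#' Plot a validation report
#'
#' Band as a ribbon, observed counts as points coloured by whether they
#' fall inside the band; a vertical line marks the first band exit.
#'
#' @param object An `ibex_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ibex_validation
#' @export
autoplot.ibex_validation <- function(object, ...) {
  tab <- object$table
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$band_lower, ymax = .data$band_upper),
      fill = "grey80"
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$inside)) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = "red"), name = "inside band"
    ) +
    ggplot2::labs(x = "year", y = "count", title = "Out-of-sample validation")
  if (!is.na(object$first_exit_year)) {
    p <- p + ggplot2::geom_vline(xintercept = object$first_exit_year,
                                 linetype = "dashed")
  }
  p
}
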