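#' One-year update of the stochastic growth model
#'
#' Applies the multiplicative update
#' `N_{t+1} = N_t * exp(a + b*D + c*P + d*D*P + eps)` where `D` is the
#' density covariate of the model's variant. Counts below the extinction
#' threshold of one animal are absorbed at zero: extinction is a state,
#' not an error. Vectorised over `n`.
#'
#' @param model An `ibex_fit` object.
#' @param n Current count(s), non-negative; values below 1 map to 0.
#' @param precip Winter precipitation (mm) of the winter ending in the
#'   target year; scalar or the same length as `n`.
#' @param eps Process-noise draw(s) on the log scale; default 0.
#'
#' @return Updated count(s), continuous (never rounded) and non-negative.
#' @export
step_population <- function(model, n, precip, eps = 0) {
  stopifnot(inherits(model, "ibex_fit"))
  if (any(n < 0)) {
    rlang::abort("counts must be non-negative.", class = "ibexdyn_error_value")
  }
  out <- numeric(length(n))
  alive <- n >= 1
  if (any(alive)) {
    na <- n[alive]
    pa <- if (length(precip) == 1) precip else precip[alive]
    ea <- if (length(eps) == 1) eps else eps[alive]
    x <- build_design(model$variant, na, pa, model$scale)
    # elementwise linear predictor (not `%*%`) so identical states give
    # bit-identical updates regardless of their position in the vector
    k <- model$coef
    lin <- k[[1]] * x[, 1] + k[[2]] * x[, 2] + k[[3]] * x[, 3] + k[[4]] * x[, 4]
    out[alive] <- na * exp(lin + ea)
  }
  out
}

#' Simulate an ensemble forecast with empirical prediction bands
#'
#' Runs `n_real` independent stochastic realizations of the fitted model
#' forward from a launch count, drawing i.i.d. Gaussian process noise
#' `eps ~ N(0, sigma^2)` each year, and summarises them by the per-year
#' ensemble mean and empirical quantile band. The default protocol (1000
#' realizations, a 90% band) matches the standard validation setup for
#' this model family. Identical seeds give bit-identical ensembles.
#'
#' @param model An `ibex_fit` object.
#' @param n_start Launch count (the last observed count of the fit window).
#' @param start_year Year of the launch count; forecasting starts the year
#'   after.
#' @param clim Climate tibble covering every forecast year.
#' @param n_real Ensemble size, at least 2; default 1000.
#' @param seed Integer seed; all noise draws flow from it.
#' @param band_level Band level in (0, 1); default 0.90. Band edges are the
#'   per-year empirical quantiles at `(1 - band_level)/2` and
#'   `1 - (1 - band_level)/2` (linear interpolation of order statistics,
#'   quantile type 7).
#' @param end_year Last forecast year; default the last climate year.
#'
#' @return An object of class `ibex_forecast`: list with `years`,
#'   `realizations` (an `n_real` x `n_years` matrix), `mean_traj`,
#'   `band_lower`, `band_upper`, `n_real`, `band_level`, `seed`,
#'   `quantile_type`, and the launch point.
#' @seealso [validate_out_of_sample()], [tidy.ibex_forecast()]
#' @export
simulate_ensemble <- function(model, n_start, start_year, clim,
                              n_real = 1000, seed, band_level = 0.90,
                              end_year = NULL) {
  stopifnot(inherits(model, "ibex_fit"))
  clim <- validate_climate(clim)
  if (n_real < 2) {
    rlang::abort("`n_real` must be at least 2.", class = "ibexdyn_error_value")
  }
  if (band_level <= 0 || band_level >= 1) {
    rlang::abort("`band_level` must lie strictly between 0 and 1.",
                 class = "ibexdyn_error_value")
  }
  seed <- as.integer(seed)
  if (is.null(end_year)) end_year <- max(clim$year)
  years <- seq.int(start_year + 1L, as.integer(end_year))
  if (end_year <= start_year) years <- integer(0)
  missing_clim <- setdiff(years, clim$year)
  if (length(missing_clim) > 0) {
    rlang::abort(
      sprintf("climate series is missing forecast year(s): %s.",
              paste(missing_clim, collapse = ", ")),
      class = "ibexdyn_error_missing_climate"
    )
  }
  n_years <- length(years)
  precip <- clim$precip[match(years, clim$year)]

  real <- matrix(numeric(0), nrow = n_real, ncol = n_years,
                 dimnames = list(NULL, years))
  if (n_years > 0) {
    withr::with_seed(seed, {
      state <- rep(as.numeric(n_start), n_real)
      for (j in seq_len(n_years)) {
        eps <- stats::rnorm(n_real, 0, model$sigma)
        state <- step_population(model, state, precip[j], eps)
        real[, j] <- state
      }
    })
  }

  probs <- c((1 - band_level) / 2, 1 - (1 - band_level) / 2)
  if (n_years > 0) {
    qs <- apply(real, 2, stats::quantile, probs = probs, type = 7, names = FALSE)
    band_lower <- qs[1, ]
    band_upper <- qs[2, ]
    mean_traj <- colMeans(real)
  } else {
    band_lower <- band_upper <- mean_traj <- numeric(0)
  }

  structure(
    list(
      years = years,
      realizations = real,
      mean_traj = unname(mean_traj),
      band_lower = unname(band_lower),
      band_upper = unname(band_upper),
      n_real = as.integer(n_real),
      band_level = band_level,
      seed = seed,
      quantile_type = 7L,
      start = list(year = as.integer(start_year), count = as.numeric(n_start)),
      variant = model$variant
    ),
    class = "ibex_forecast"
  )
}

#' @export
print.ibex_forecast <- function(x, ...) {
  cat(sprintf("<ibex_forecast> %d realizations, %d year(s), %.0f%% band, seed %d\n",
              x$n_real, length(x$years), 100 * x$band_level, x$seed))
  if (length(x$years) > 0) print(tidy.ibex_forecast(x))
  invisible(x)
}

#' Tidy an ensemble forecast
#'
#' @param x An `ibex_forecast` object.
#' @param ... Unused.
#' @return A tibble with one row per forecast year: `year`, `mean`,
#'   `band_lower`, `band_upper`.
#' @method tidy ibex_forecast
#' @export
tidy.ibex_forecast <- function(x, ...) {
  tibble::tibble(
    year = x$years,
    mean = x$mean_traj,
    band_lower = x$band_lower,
    band_upper = x$band_upper
  )
}

#' Plot an ensemble forecast
#'
#' Ribbon for the empirical band, line for the ensemble mean, and the
#' observed census as points when supplied.
#'
#' @param object An `ibex_forecast` object.
#' @param observed Optional census tibble (`year`, `count`) to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ibex_forecast
#' @export
autoplot.ibex_forecast <- function(object, observed = NULL, ...) {
  df <- tidy.ibex_forecast(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$band_lower, ymax = .data$band_upper),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.8) +
    ggplot2::labs(
      x = "year", y = "count",
      title = sprintf("Ensemble forecast (%d realizations, %.0f%% band)",
                      object$n_real, 100 * object$band_level)
    )
  if (!is.null(observed)) {
    obs <- validate_population(observed)
    p <- p + ggplot2::geom_point(
      data = obs, ggplot2::aes(x = .data$year, y = .data$count)
    )
  }
  p
}
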