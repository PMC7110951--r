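#' Replicate simulation studies of the fit/forecast/detect protocol
#'
#' These functions script the package's Monte-Carlo evaluation studies as
#' reproducible experiments driven by a single master seed (replicates take
#' child seeds at fixed offsets, see [child_seed()]). The study conditions
#' default to the package's reference scenario ([scenario_spec()]): a
#' colony launched at 2370 animals, fitted on a 20-year calibration window
#' and forecast with 1000-realization ensembles and a 90% band.
#'
#' * `study_band_bookkeeping()` checks the empirical-quantile bookkeeping
#'   of one ensemble: per forecast year, how many realizations fall within
#'   the closed band and how many fall strictly below it.
#' * `study_parameter_recovery()` refits the generating model on replicate
#'   synthetic series and reports the median absolute error of each
#'   coefficient — consistency shows as errors shrinking with series
#'   length.
#' * `study_nominal_coverage()` validates forecasts against observation
#'   trajectories drawn from the *same* model and reports per-replicate
#'   band coverage, whose long-run mean should sit at the band level.
#' * `study_detection()` measures, per removal strength, how often the
#'   first band exit falls within `detect_horizon` years of the
#'   intervention changepoint (placed in the first forecast year).
#'
#' @param seed Master integer seed.
#' @param n_real Ensemble size.
#' @param band_level Band level.
#' @param n_years Series length in years (for `study_band_bookkeeping()`
#'   and `study_nominal_coverage()`, the forecast horizon; for
#'   `study_parameter_recovery()`, the fitted series length).
#' @param n_rep Number of Monte-Carlo replicates.
#' @param sigma Process-noise standard deviation of the generating model.
#' @param removal_rates Numeric vector of per-year removal fractions.
#' @param fit_years Length of the calibration window in census years.
#' @param horizon Number of forecast years after the changepoint.
#' @param detect_horizon Detection window: an exit in
#'   `[changepoint, changepoint + detect_horizon]` counts as localized.
#'
#' @return A tibble; see each function's `@return` below.
#' @name ibex_studies
NULL

#' @rdname ibex_studies
#' @return For `study_band_bookkeeping()`: one row per forecast year with
#'   `year`, `n_inside_closed`, `n_below_lower`, `n_real`.
#' @export
study_band_bookkeeping <- function(seed, n_real = 1000, band_level = 0.90,
                                   n_years = 15, sigma = 0.07) {
  spec <- scenario_spec(sigma = sigma, n_years = n_years + 1,
                        seed = child_seed(seed, 11))
  clim <- generate_climate(spec)
  model <- scenario_model(spec)
  fc <- simulate_ensemble(model, spec$n0, spec$start_year, clim,
                          n_real = n_real, seed = child_seed(seed, 12),
                          band_level = band_level)
  purrr::map_dfr(seq_along(fc$years), function(j) {
    x <- fc$realizations[, j]
    tibble::tibble(
      year = fc$years[j],
      n_inside_closed = sum(x >= fc$band_lower[j] & x <= fc$band_upper[j]),
      n_below_lower = sum(x < fc$band_lower[j]),
      n_real = fc$n_real
    )
  })
}

#' @rdname ibex_studies
#' @return For `study_parameter_recovery()`: one row per coefficient with
#'   `term`, `median_abs_error`, `n_years`, `n_rep`.
#' @export
study_parameter_recovery <- function(n_years, n_rep = 500, seed,
                                     sigma = 0.07) {
  truth <- scenario_spec(sigma = sigma, n_years = n_years)
  true_coef <- c(a = truth$a, b = truth$b, c = truth$c, d = truth$d)
  errs <- purrr::map(seq_len(n_rep), function(i) {
    spec <- scenario_spec(sigma = sigma, n_years = n_years,
                          seed = child_seed(seed, i))
    clim <- generate_climate(spec)
    cen <- generate_census(spec, clim)
    fit <- fit_model(cen$observed, clim, "D2")
    abs(fit$coef - true_coef)
  })
  mat <- do.call(rbind, errs)
  tibble::tibble(
    term = c("a", "b", "c", "d"),
    median_abs_error = apply(mat, 2, stats::median),
    n_years = n_years,
    n_rep = n_rep
  )
}

#' @rdname ibex_studies
#' @return For `study_nominal_coverage()`: one row per replicate with
#'   `replicate` and `coverage`.
#' @export
study_nominal_coverage <- function(n_rep = 500, seed, n_real = 1000,
                                   band_level = 0.90, n_years = 15,
                                   sigma = 0.07) {
  purrr::map_dfr(seq_len(n_rep), function(i) {
    spec <- scenario_spec(sigma = sigma, n_years = n_years + 1,
                          seed = child_seed(seed, 2 * i))
    clim <- generate_climate(spec)
    model <- scenario_model(spec)
    # one observation trajectory and one ensemble from the same model
    obs <- generate_census(spec, clim)$observed
    fc <- simulate_ensemble(model, spec$n0, spec$start_year, clim,
                            n_real = n_real,
                            seed = child_seed(seed, 2 * i + 1),
                            band_level = band_level)
    v <- validate_out_of_sample(fc, obs)
    tibble::tibble(replicate = i, coverage = v$coverage)
  })
}

#' @rdname ibex_studies
#' @return For `study_detection()`: one row per removal strength with
#'   `removal_rate`, `detection_rate`, `n_rep`; a replicate counts as
#'   detected when the first band exit falls within the detection window
#'   after the changepoint.
#' @export
study_detection <- function(removal_rates = c(0.05, 0.10, 0.20),
                            n_rep = 200, seed, n_real = 500,
                            band_level = 0.90, fit_years = 20,
                            horizon = 15, detect_horizon = 3,
                            sigma = 0.07) {
  purrr::map_dfr(seq_along(removal_rates), function(k) {
    rate <- removal_rates[k]
    hits <- purrr::map_lgl(seq_len(n_rep), function(i) {
      s <- child_seed(seed, 1000 * k + 2 * i)
      spec <- scenario_spec(
        sigma = sigma, n_years = fit_years + horizon,
        changepoint_year = 1923L + fit_years, removal_rate = rate,
        seed = s
      )
      clim <- generate_climate(spec)
      cen <- generate_census(spec, clim)
      exp <- run_windowed(
        cen$observed, clim, "D2",
        fit_end_year = spec$changepoint_year - 1L,
        n_real = n_real, seed = child_seed(seed, 1000 * k + 2 * i + 1),
        band_level = band_level
      )
      exit <- first_band_exit(exp$validation)
      !is.na(exit) && exit >= spec$changepoint_year &&
        exit <= spec$changepoint_year + detect_horizon
    })
    tibble::tibble(removal_rate = rate, detection_rate = mean(hits),
                   n_rep = n_rep)
  })
}
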