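#' Specify a synthetic census scenario
#'
#' Bundles the true model parameters and the study conditions under which
#' synthetic census and climate series are generated. The defaults emulate
#' an interwar Gran-Paradiso-like regime: a colony of a few thousand
#' animals with mild density dependence (equilibrium near 3900 under
#' average winters), a weak negative precipitation effect, and alpine
#' valley-station winter totals around 450 mm with strong interannual
#' variation. They are calibration choices of this package, documented in
#' the methods vignette, not measured archival values.
#'
#' @param variant `"D1"` or `"D2"`; default `"D2"`.
#' @param a,b,c,d True coefficients of the log-growth linear predictor
#'   (intercept, density, precipitation per mm, interaction).
#' @param sigma Process-noise standard deviation on the log growth rate.
#' @param n0 Initial count; default 2370, or 25 in founder mode.
#' @param n_years Number of simulated years; default 20.
#' @param start_year First calendar year; default 1923.
#' @param climate_mean,climate_sd Mean and standard deviation (mm) of the
#'   truncated-Gaussian winter totals.
#' @param changepoint_year Optional year from which the removal
#'   intervention acts.
#' @param removal_rate Optional fraction in `[0, 1)` removed from the
#'   count each year from the changepoint onwards (a survival-fraction
#'   model of poaching/harvest pressure).
#' @param founder Founder-population mode: a small introduced colony far
#'   below carrying capacity, growing near-exponentially.
#' @param gap_years Optional years deleted from the *observed* output
#'   (the latent trajectory is untouched), emulating missed censuses.
#' @param seed Integer master seed; climate, census and warden draws use
#'   fixed child seeds derived from it (see [child_seed()]).
#'
#' @return An object of class `ibex_scenario` (a validated list).
#' @export
scenario_spec <- function(variant = "D2",
                          a = 1.104, b = -0.12, c = -8e-4, d = 6.7e-5,
                          sigma = 0.07,
                          n0 = if (founder) 25 else 2370,
                          n_years = 20, start_year = 1923,
                          climate_mean = 450, climate_sd = 120,
                          changepoint_year = NULL, removal_rate = NULL,
                          founder = FALSE, gap_years = NULL, seed = 1L) {
  variant <- match_variant(variant)
  if (sigma < 0) {
    rlang::abort("`sigma` must be non-negative.", class = "ibexdyn_error_value")
  }
  if (n0 <= 0) {
    rlang::abort("`n0` must be positive.", class = "ibexdyn_error_value")
  }
  if (climate_sd < 0 || climate_mean <= 0) {
    rlang::abort("`climate_mean` must be positive and `climate_sd` non-negative.",
                 class = "ibexdyn_error_value")
  }
  years <- seq.int(start_year, start_year + n_years - 1L)
  if (!is.null(removal_rate)) {
    if (removal_rate < 0 || removal_rate >= 1) {
      rlang::abort("`removal_rate` must lie in [0, 1).",
                   class = "ibexdyn_error_value")
    }
    if (is.null(changepoint_year)) {
      rlang::abort("`removal_rate` requires a `changepoint_year`.",
                   class = "ibexdyn_error_value")
    }
  }
  if (!is.null(changepoint_year) && !changepoint_year %in% years) {
    rlang::abort("`changepoint_year` must fall inside the simulated window.",
                 class = "ibexdyn_error_value")
  }
  structure(
    list(variant = variant, a = a, b = b, c = c, d = d, sigma = sigma,
         n0 = n0, n_years = as.integer(n_years),
         start_year = as.integer(start_year),
         climate_mean = climate_mean, climate_sd = climate_sd,
         changepoint_year = if (is.null(changepoint_year)) NULL
                            else as.integer(changepoint_year),
         removal_rate = removal_rate, founder = isTRUE(founder),
         gap_years = if (is.null(gap_years)) NULL else as.integer(gap_years),
         seed = as.integer(seed)),
    class = "ibex_scenario"
  )
}

# the scenario's true parameters as a model object
scenario_model <- function(spec) {
  make_model(spec$variant, spec$a, spec$b, spec$c, spec$d, spec$sigma)
}

#' Derive a reproducible child seed
#'
#' All randomness in a scenario or replicate study flows from one master
#' seed; independent streams (climate, census, wardens, replicates) take
#' child seeds at fixed offsets so every experiment is reproducible from a
#' single integer. The result always fits a 32-bit integer.
#'
#' @param seed Master integer seed.
#' @param index Non-negative stream index.
#' @return An integer seed.
#' @export
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 + as.numeric(index) * 104729) %%
               2147483647)
}

#' Generate a synthetic winter-precipitation series
#'
#' Independent truncated-at-zero Gaussian annual winter totals (winters
#' treated as exchangeable: no interannual autocorrelation). With
#' `climate_sd = 0` the series is constant at the mean.
#'
#' @param spec An `ibex_scenario`.
#' @return A climate tibble (`year`, `precip`) covering the scenario
#'   window.
#' @export
generate_climate <- function(spec) {
  stopifnot(inherits(spec, "ibex_scenario"))
  years <- seq.int(spec$start_year, spec$start_year + spec$n_years - 1L)
  if (spec$climate_sd == 0) {
    precip <- rep(spec$climate_mean, length(years))
  } else {
    precip <- withr::with_seed(child_seed(spec$seed, 1), {
      # inverse-CDF draw from the Gaussian truncated below at zero
      lo <- stats::pnorm(0, spec$climate_mean, spec$climate_sd)
      u <- stats::runif(length(years), lo, 1)
      stats::qnorm(u, spec$climate_mean, spec$climate_sd)
    })
  }
  climate_series(years, precip)
}

#' Generate a synthetic census series (with its no-intervention twin)
#'
#' Forward-simulates the scenario's true growth model over the supplied
#' climate. When a removal intervention is active, the count reported for
#' each year from the changepoint onwards is multiplied by a further
#' factor of `1 - removal_rate`, so `k` years into the intervention the
#' observed count equals the latent count times `(1 - removal_rate)^k`
#' (the changepoint year itself is the first removal year). The latent
#' twin is the identical trajectory with no removal, so the pair differ
#' only from the changepoint on. `gap_years` rows are deleted from the
#' observed output only. Counts are kept continuous; rounding happens
#' only at serialization time.
#'
#' @param spec An `ibex_scenario`.
#' @param clim Climate tibble covering the scenario years; default
#'   `generate_climate(spec)`.
#' @return A list with census tibbles `observed` (gaps applied, removal
#'   applied) and `latent` (the no-intervention, gap-free twin).
#' @export
generate_census <- function(spec, clim = generate_climate(spec)) {
  stopifnot(inherits(spec, "ibex_scenario"))
  clim <- validate_climate(clim)
  years <- seq.int(spec$start_year, spec$start_year + spec$n_years - 1L)
  missing_clim <- setdiff(years[-1], clim$year)
  if (length(missing_clim) > 0) {
    rlang::abort(
      sprintf("climate series is missing scenario year(s): %s.",
              paste(missing_clim, collapse = ", ")),
      class = "ibexdyn_error_missing_climate"
    )
  }
  model <- scenario_model(spec)
  precip <- clim$precip[match(years, clim$year)]
  eps <- withr::with_seed(child_seed(spec$seed, 2),
                          stats::rnorm(length(years) - 1, 0, spec$sigma))

  latent <- numeric(length(years))
  latent[1] <- spec$n0
  for (j in seq_along(years)[-1]) {
    latent[j] <- step_population(model, latent[j - 1], precip[j], eps[j - 1])
  }
  observed <- latent
  if (!is.null(spec$removal_rate)) {
    k <- pmax(0, years - spec$changepoint_year + 1)
    observed <- latent * (1 - spec$removal_rate)^k
  }
  obs <- tibble::tibble(year = years, count = observed)
  if (!is.null(spec$gap_years)) {
    obs <- dplyr::filter(obs, !.data$year %in% spec$gap_years)
  }
  list(observed = obs, latent = tibble::tibble(year = years, count = latent))
}

#' Generate a synthetic warden-headcount series
#'
#' A stable headcount with a step drop at `drop_year` plus small seeded
#' integer jitter — the personnel regime of a park whose warden corps is
#' cut at a management change.
#'
#' @param n_years Number of years.
#' @param base Baseline headcount; default 40.
#' @param drop_year Year the step drop takes effect.
#' @param drop_size Size of the drop; default 16; must satisfy
#'   `base > drop_size >= 0`.
#' @param jitter Maximum absolute integer jitter per year; 0 for an exact
#'   step series. Default 1.
#' @param seed Integer seed for the jitter.
#' @param start_year First year; default 1923.
#' @return A tibble (`year`, `wardens`).
#' @export
generate_wardens <- function(n_years, base = 40, drop_year,
                             drop_size = 16, jitter = 1, seed = 1L,
                             start_year = 1923) {
  if (drop_size < 0 || base <= drop_size) {
    rlang::abort("`base` must exceed `drop_size`, and `drop_size` must be >= 0.",
                 class = "ibexdyn_error_value")
  }
  years <- seq.int(start_year, start_year + n_years - 1L)
  level <- base - drop_size * (years >= drop_year)
  noise <- if (jitter > 0) {
    withr::with_seed(child_seed(seed, 3),
                     sample(seq.int(-jitter, jitter), length(years),
                            replace = TRUE))
  } else {
    rep(0L, length(years))
  }
  tibble::tibble(year = as.integer(years),
                 wardens = pmax(0L, as.integer(level + noise)))
}
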