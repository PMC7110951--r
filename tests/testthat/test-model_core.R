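test_that("log growth rates follow the closed form and are attributed to the later year", {
  # constant series: zero growth
  flat <- population_series(1930:1931, c(2000, 2000))
  expect_equal(growth_rates(flat)$r, 0)

  # a halving gives -ln 2
  half <- population_series(1930:1931, c(100, 50))
  expect_equal(growth_rates(half)$r, -log(2))

  # geometric interpolation between the 1922 and 1933 census values:
  # every annual rate equals ln(3865/2370)/11
  years <- 1922:1933
  counts <- 2370 * (3865 / 2370)^((years - 1922) / 11)
  gr <- growth_rates(population_series(years, counts))
  expect_equal(gr$year, 1923:1933)
  expect_equal(gr$r, rep(log(3865 / 2370) / 11, 11), tolerance = 1e-12)
  expect_equal(gr$r[1], 0.04446, tolerance = 1e-4)
})

test_that("growth pairs spanning a gap are skipped, never interpolated", {
  pop <- population_series(c(1940:1943, 1945, 1946), c(100, 110, 120, 130, 90, 95))
  gr <- growth_rates(pop)
  expect_equal(gr$year, c(1941:1943, 1946))
  expect_false(1945 %in% gr$year)

  # too gappy: no consecutive pair at all
  sparse <- population_series(c(1930, 1932, 1934), c(10, 20, 30))
  expect_equal(nrow(growth_rates(sparse)), 0)

  # a zero count in a used pair is an error, not a -Inf
  dead <- population_series(1930:1932, c(50, 0, 10))
  expect_error(growth_rates(dead), class = "ibexdyn_error_zero_count")
})

test_that("design rows transform density by variant", {
  expect_equal(design_row("D1", n_prev = 100, precip = 500),
               c(intercept = 1, density = 100, precip = 500,
                 density_precip = 50000))
  expect_equal(design_row("D2", n_prev = exp(2), precip = 10),
               c(intercept = 1, density = 2, precip = 10,
                 density_precip = 20))
  expect_equal(design_row("D2", n_prev = 1, precip = 300),
               c(intercept = 1, density = 0, precip = 300,
                 density_precip = 0))
  expect_error(design_row("D1", n_prev = 0, precip = 10),
               class = "ibexdyn_error_value")
  expect_error(design_row("D3", 10, 10), class = "ibexdyn_error_value")
})

test_that("noise-free synthetic series are refit exactly for both variants", {
  for (variant in c("D1", "D2")) {
    truth <- if (variant == "D1") {
      c(a = 0.9, b = -2e-4, c = -6e-4, d = 1.2e-7)
    } else {
      c(a = 1.104, b = -0.12, c = -8e-4, d = 6.7e-5)
    }
    gen <- noise_free_series(variant, truth["a"], truth["b"],
                             truth["c"], truth["d"])
    fit <- fit_model(gen$pop, gen$clim, variant = variant)
    expect_lt(max(abs(fit$coef - truth)), 1e-8)
    expect_lt(fit$sigma, 1e-8)
    expect_equal(fit$n_obs, nrow(gen$pop) - 1)
  }
})

test_that("fitted coefficients match the brute-force normal-equations oracle", {
  pop <- read_series(fixture_path("synthetic_census_8yr.csv"), "census")
  clim <- read_series(fixture_path("synthetic_climate_8yr.csv"), "climate")
  for (variant in c("D1", "D2")) {
    fit <- fit_model(pop, clim, variant = variant)
    gr <- growth_rates(pop)
    df <- dplyr::inner_join(gr, clim, by = "year")
    x <- ibexdyn:::design_matrix(variant, df$n_prev, df$precip)
    beta <- ne_solve(x, df$r)
    expect_rel_equal(unname(fit$coef), unname(beta), 1e-8)
    rss <- sum((df$r - x %*% beta)^2)
    expect_equal(fit$sigma, sqrt(rss / (nrow(df) - 4)), tolerance = 1e-10)
  }
})

test_that("degenerate designs and short windows are rejected with named causes", {
  # constant counts and constant precipitation: everything collinear
  pop <- population_series(1923:1932, rep(3000, 10))
  clim <- climate_series(1923:1932, rep(450, 10))
  err <- expect_error(fit_model(pop, clim, "D2"),
                      class = "ibexdyn_error_singular")
  expect_match(conditionMessage(err), "density|precip")

  # fewer than 5 growth observations for a 4-parameter model
  short <- population_series(1923:1927, c(100, 110, 125, 130, 150))
  clim5 <- climate_series(1923:1927, c(400, 500, 350, 450, 420))
  expect_error(fit_model(short, clim5, "D2"),
               class = "ibexdyn_error_too_few_obs")

  # climate missing a growth year
  gen <- noise_free_series("D2", 1, -0.1, -1e-3, 1e-4)
  expect_error(
    fit_model(gen$pop, dplyr::filter(gen$clim, year != 1928), "D2"),
    class = "ibexdyn_error_missing_climate"
  )

  # window endpoints must be census years
  expect_error(fit_model(gen$pop, gen$clim, "D2", train_window = c(1900, 1930)),
               class = "ibexdyn_error_value")
})

test_that("optional covariate scaling leaves fitted dynamics unchanged", {
  gen <- noise_free_series("D2", 1.104, -0.12, -8e-4, 6.7e-5)
  plain <- fit_model(gen$pop, gen$clim, "D2")
  scaled <- fit_model(gen$pop, gen$clim, "D2", scale_covariates = TRUE)
  expect_false(is.null(scaled$scale))
  # the one-step prediction is invariant to the stored transform
  expect_equal(step_population(scaled, 2500, 430),
               step_population(plain, 2500, 430), tolerance = 1e-8)
  expect_equal(scaled$sigma, plain$sigma, tolerance = 1e-10)
})

test_that("the one-step update has the stated closed form and absorbs extinction", {
  null_model <- ibexdyn:::make_model("D2", 0, 0, 0, 0, sigma = 0)
  expect_equal(step_population(null_model, 500, 400), 500)

  doubling <- ibexdyn:::make_model("D2", log(2), 0, 0, 0, sigma = 0)
  expect_equal(step_population(doubling, 100, 0), 200)
  expect_equal(step_population(doubling, 100, 0, eps = log(3 / 2)), 300)

  # below one animal the state is absorbed at zero
  expect_equal(step_population(doubling, 0.5, 400), 0)
  expect_equal(step_population(doubling, 0, 400), 0)
  expect_error(step_population(doubling, -1, 400),
               class = "ibexdyn_error_value")
})

test_that("a zero-noise ensemble is degenerate and bands collapse on the mean", {
  gen <- noise_free_series("D2", 1.104, -0.12, -8e-4, 6.7e-5, n_years = 15)
  fc <- simulate_ensemble(gen$model, n_start = 2370, start_year = 1923,
                          clim = gen$clim, n_real = 50, seed = 4)
  expect_equal(fc$band_lower, fc$mean_traj)
  expect_equal(fc$band_upper, fc$mean_traj)
  expect_true(all(apply(fc$realizations, 2, function(x) length(unique(x)) == 1)))
})

test_that("identical seeds give bit-identical ensembles and different seeds do not", {
  gen <- noise_free_series("D2", 1.104, -0.12, -8e-4, 6.7e-5, n_years = 15)
  model <- ibexdyn:::make_model("D2", 1.104, -0.12, -8e-4, 6.7e-5, sigma = 0.07)
  a <- simulate_ensemble(model, 2370, 1923, gen$clim, n_real = 100, seed = 42)
  b <- simulate_ensemble(model, 2370, 1923, gen$clim, n_real = 100, seed = 42)
  c <- simulate_ensemble(model, 2370, 1923, gen$clim, n_real = 100, seed = 43)
  expect_identical(a$realizations, b$realizations)
  expect_identical(a$band_lower, b$band_lower)
  expect_false(identical(a$realizations, c$realizations))
})

test_that("empirical band bookkeeping brackets the nominal level each year", {
  gen <- noise_free_series("D2", 1.104, -0.12, -8e-4, 6.7e-5, n_years = 12)
  model <- ibexdyn:::make_model("D2", 1.104, -0.12, -8e-4, 6.7e-5, sigma = 0.1)
  fc <- simulate_ensemble(model, 2370, 1923, gen$clim, n_real = 200, seed = 9,
                          band_level = 0.8)
  for (j in seq_along(fc$years)) {
    x <- fc$realizations[, j]
    open <- mean(x > fc$band_lower[j] & x < fc$band_upper[j])
    closed <- mean(x >= fc$band_lower[j] & x <= fc$band_upper[j])
    expect_lte(open, 0.8 + 1e-12)
    expect_gte(closed, 0.8 - 1e-12)
    expect_lte(fc$band_lower[j], fc$band_upper[j])
  }
})

test_that("extinct realizations stay extinct", {
  # strong decline with heavy noise drives some realizations to zero
  model <- ibexdyn:::make_model("D2", -1.5, 0, 0, 0, sigma = 0.5)
  clim <- climate_series(1924:1943, rep(450, 20))
  fc <- simulate_ensemble(model, 50, 1923, clim, n_real = 200, seed = 3)
  real <- fc$realizations
  expect_true(any(real == 0))
  for (i in seq_len(nrow(real))) {
    zeros <- which(real[i, ] == 0)
    if (length(zeros) > 0) {
      expect_true(all(real[i, zeros[1]:ncol(real)] == 0))
    }
  }
  expect_true(all(real >= 0))
})

test_that("with a negative precipitation effect, wetter winters never help", {
  model <- ibexdyn:::make_model("D2", 0.74, -0.09, -5e-4, 0, sigma = 0.05)
  clim <- climate_series(1924:1938, 400 + 100 * sin(1:15))
  wetter <- climate_series(clim$year, clim$precip + 150)
  a <- simulate_ensemble(model, 2370, 1923, clim, n_real = 100, seed = 21)
  b <- simulate_ensemble(model, 2370, 1923, wetter, n_real = 100, seed = 21)
  expect_true(all(b$realizations <= a$realizations + 1e-9))
})

test_that("forecast years missing from climate are reported by year", {
  model <- ibexdyn:::make_model("D2", 0.7, -0.09, -5e-4, 0, sigma = 0.05)
  clim <- climate_series(c(1924:1927, 1930), rep(450, 5))
  err <- expect_error(
    simulate_ensemble(model, 2000, 1923, clim, n_real = 10, seed = 1,
                      end_year = 1930),
    class = "ibexdyn_error_missing_climate"
  )
  expect_match(conditionMessage(err), "1928, 1929")
})

test_that("validation flags band exits and ties count as inside", {
  model <- ibexdyn:::make_model("D2", 0.74, -0.09, -5e-4, 0, sigma = 0.05)
  clim <- climate_series(1924:1933, rep(450, 10))
  fc <- simulate_ensemble(model, 2370, 1923, clim, n_real = 500, seed = 8)

  # the ensemble mean of a noisy ensemble sits inside its own band
  center <- population_series(fc$years, fc$mean_traj)
  v <- validate_out_of_sample(fc, center)
  expect_equal(v$coverage, 1)
  expect_true(is.na(first_band_exit(v)))

  # one constructed exit just above the band in 1928
  obs <- fc$mean_traj
  obs[fc$years == 1928] <- fc$band_upper[fc$years == 1928] + 1
  v2 <- validate_out_of_sample(fc, population_series(fc$years, obs))
  expect_equal(v2$coverage, (length(fc$years) - 1) / length(fc$years))
  expect_equal(first_band_exit(v2), 1928L)

  # a count exactly on the band edge is inside (closed interval)
  obs3 <- fc$mean_traj
  obs3[1] <- fc$band_upper[1]
  v3 <- validate_out_of_sample(fc, population_series(fc$years, obs3))
  expect_equal(v3$coverage, 1)

  # the first outside year wins even when later years return inside
  flags <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  obs4 <- fc$mean_traj[1:5]
  obs4[!flags] <- fc$band_upper[1:5][!flags] + 10
  v4 <- validate_out_of_sample(fc, population_series(1924:1928, obs4))
  expect_equal(first_band_exit(v4), 1926L)

  # unobserved forecast years are skipped, disjoint years error
  part <- validate_out_of_sample(fc, population_series(c(1925, 1927),
                                                       fc$mean_traj[c(2, 4)]))
  expect_equal(nrow(part$table), 2)
  expect_error(
    validate_out_of_sample(fc, population_series(1950:1952, c(1, 2, 3))),
    class = "ibexdyn_error_no_overlap"
  )
})

test_that("tidy and glance methods return the documented shapes", {
  gen <- noise_free_series("D2", 1.104, -0.12, -8e-4, 6.7e-5)
  fit <- fit_model(gen$pop, gen$clim, "D2")
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "density", "precip", "density_precip"))
  expect_equal(nrow(glance(fit)), 1)

  fc <- simulate_ensemble(fit, 2370, max(gen$pop$year), gen$clim,
                          n_real = 20, seed = 2,
                          end_year = max(gen$pop$year))
  expect_equal(nrow(tidy(fc)), 0) # fit window runs to the series end
})
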