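# Independent oracles and small builders shared across the suite.

# brute-force normal-equations solve, independent of the fitting path;
# columns are equilibrated to unit norm first (a pure rescaling of the
# same linear system) so the explicit t(X)X inversion stays well posed
ne_solve <- function(x, y) {
  s <- sqrt(colSums(x^2))
  xs <- sweep(x, 2, s, "/")
  beta_s <- solve(t(xs) %*% xs, t(xs) %*% y)[, 1]
  beta_s / s
}

# census series generated exactly (no noise) from known coefficients,
# with counts varying enough to keep the design full rank
noise_free_series <- function(variant, a, b, c, d, n_years = 12,
                              n0 = 2000, precip = NULL, start_year = 1923) {
  years <- seq.int(start_year, start_year + n_years - 1)
  if (is.null(precip)) {
    precip <- 400 + 150 * sin(seq_along(years)) + 10 * seq_along(years)
  }
  model <- ibexdyn:::make_model(variant, a, b, c, d, sigma = 0)
  count <- numeric(n_years)
  count[1] <- n0
  for (j in 2:n_years) {
    count[j] <- step_population(model, count[j - 1], precip[j])
  }
  list(
    pop = population_series(years, count),
    clim = climate_series(years, precip),
    model = model
  )
}

# random full-rank regression instance on the growth-rate scale
random_fit_instance <- function(n_obs, variant = sample(c("D1", "D2"), 1)) {
  years <- seq.int(1923, length.out = n_obs + 1)
  counts <- exp(runif(n_obs + 1, log(200), log(5000)))
  precip <- runif(n_obs + 1, 200, 700)
  pop <- population_series(years, counts)
  clim <- climate_series(years, precip)
  list(pop = pop, clim = clim, variant = variant)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "ibexdyn", mustWork = TRUE)
}
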