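#' Covariate row of the growth model
#'
#' The linear predictor of the log growth rate uses an intercept, a density
#' term, winter precipitation, and the density-precipitation product. The
#' density term is the previous year's count itself under variant `"D1"`
#' and its natural logarithm under variant `"D2"` (the park area is
#' constant, so count is proportional to density).
#'
#' @param variant `"D1"` (raw density) or `"D2"` (log density).
#' @param n_prev Previous year's count; must be positive.
#' @param precip Winter precipitation in mm; must be non-negative.
#'
#' @return A named numeric vector `(intercept, density, precip,
#'   density_precip)`.
#' @export
#' @examples
#' design_row("D1", n_prev = 100, precip = 500)
#' design_row("D2", n_prev = exp(2), precip = 10)
design_row <- function(variant, n_prev, precip) {
  variant <- match_variant(variant)
  if (length(n_prev) != 1 || length(precip) != 1) {
    rlang::abort("`design_row()` is scalar; use the fitting interface for series.",
                 class = "ibexdyn_error_value")
  }
  drop(design_matrix(variant, n_prev, precip))
}

design_matrix <- function(variant, n_prev, precip) {
  if (any(n_prev <= 0)) {
    rlang::abort("previous-year counts must be positive to form the density covariate.",
                 class = "ibexdyn_error_value")
  }
  if (any(precip < 0)) {
    rlang::abort("precipitation must be non-negative.",
                 class = "ibexdyn_error_value")
  }
  d <- if (variant == "D1") n_prev else log(n_prev)
  cbind(intercept = 1, density = d, precip = precip, density_precip = d * precip)
}

match_variant <- function(variant) {
  if (length(variant) != 1 || !variant %in% c("D1", "D2")) {
    rlang::abort('`variant` must be "D1" (raw density) or "D2" (log density).',
                 class = "ibexdyn_error_value")
  }
  variant
}

#' Fit the stochastic log-growth model to census and climate series
#'
#' Regresses annual log growth rates on the previous year's density (raw or
#' log, by variant), the winter precipitation of the winter ending in the
#' growth year, and their product, by ordinary least squares. The residual
#' standard deviation `sigma` (with an `n - 4` denominator) becomes the
#' process-noise scale used by [simulate_ensemble()].
#'
#' @param pop Census tibble (`year`, `count`).
#' @param clim Climate tibble (`year`, `precip`); every growth year used in
#'   the fit must have a matching climate year.
#' @param variant `"D1"` or `"D2"`; default `"D2"`.
#' @param train_window Length-2 integer vector `(first year, last year)`
#'   delimiting the fit; both endpoints must be years present in `pop`.
#'   Default: the full census range.
#' @param scale_covariates If `TRUE`, centre and scale the density and
#'   precipitation covariates before fitting; the transform is stored on
#'   the fitted object and re-applied during simulation. Default `FALSE`.
#'
#' @return An object of class `ibex_fit`: a list with elements `variant`,
#'   `coef` (named `a`, `b`, `c`, `d` for intercept, density, precipitation
#'   and interaction), `sigma`, `std_error`, `train_window`, `n_obs`,
#'   `r_squared`, `scale` and `data` (the fitting frame).
#' @seealso [tidy.ibex_fit()], [glance.ibex_fit()], [simulate_ensemble()]
#' @export
fit_model <- function(pop, clim, variant = "D2", train_window = NULL,
                      scale_covariates = FALSE) {
  variant <- match_variant(variant)
  pop <- validate_population(pop)
  clim <- validate_climate(clim)

  if (is.null(train_window)) {
    train_window <- range(pop$year)
  }
  train_window <- as.integer(train_window)
  if (length(train_window) != 2 || train_window[1] > train_window[2]) {
    rlang::abort("`train_window` must be (first year, last year) with first <= last.",
                 class = "ibexdyn_error_value")
  }
  if (!all(train_window %in% pop$year)) {
    rlang::abort("`train_window` endpoints must be years present in the census series.",
                 class = "ibexdyn_error_value")
  }

  sub <- dplyr::filter(pop, .data$year >= train_window[1],
                       .data$year <= train_window[2])
  gr <- growth_rates(sub)
  if (nrow(gr) < 5) {
    rlang::abort(
      sprintf("only %d usable growth observations in %d-%d; at least 5 are required for a 4-parameter fit.",
              nrow(gr), train_window[1], train_window[2]),
      class = "ibexdyn_error_too_few_obs"
    )
  }
  missing_clim <- setdiff(gr$year, clim$year)
  if (length(missing_clim) > 0) {
    rlang::abort(
      sprintf("no climate record for growth year(s): %s.",
              paste(missing_clim, collapse = ", ")),
      class = "ibexdyn_error_missing_climate"
    )
  }
  df <- dplyr::inner_join(gr, clim, by = "year")

  scale_info <- NULL
  n_for_design <- df$n_prev
  p_for_design <- df$precip
  if (scale_covariates) {
    d_raw <- if (variant == "D1") df$n_prev else log(df$n_prev)
    scale_info <- list(
      density_center = mean(d_raw), density_scale = stats::sd(d_raw),
      precip_center = mean(df$precip), precip_scale = stats::sd(df$precip)
    )
  }
  x <- build_design(variant, n_for_design, p_for_design, scale_info)

  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    collinear <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    rlang::abort(
      sprintf("singular fit: column(s) %s are collinear with the rest of the design.",
              paste(sprintf("`%s`", collinear), collapse = ", ")),
      class = "ibexdyn_error_singular"
    )
  }

  beta <- qr.coef(qx, df$r)
  resid <- df$r - drop(x %*% beta)
  n_obs <- nrow(df)
  rss <- sum(resid^2)
  sigma <- sqrt(rss / (n_obs - 4))
  tss <- sum((df$r - mean(df$r))^2)
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(xtx_inv)) * sigma

  coef <- stats::setNames(as.numeric(beta), c("a", "b", "c", "d"))
  structure(
    list(
      variant = variant,
      coef = coef,
      sigma = sigma,
      std_error = stats::setNames(as.numeric(se), c("a", "b", "c", "d")),
      train_window = train_window,
      n_obs = n_obs,
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      scale = scale_info,
      data = df
    ),
    class = "ibex_fit"
  )
}

# design with optional stored centring/scaling of the covariates
build_design <- function(variant, n_prev, precip, scale_info = NULL) {
  x <- design_matrix(variant, n_prev, precip)
  if (!is.null(scale_info)) {
    d <- (x[, "density"] - scale_info$density_center) / scale_info$density_scale
    p <- (x[, "precip"] - scale_info$precip_center) / scale_info$precip_scale
    x <- cbind(intercept = 1, density = d, precip = p, density_precip = d * p)
  }
  x
}

# bare model object from known parameters (used by the synthetic generator
# and in tests); bypasses fitting
make_model <- function(variant, a, b, c, d, sigma,
                       train_window = c(NA_integer_, NA_integer_),
                       n_obs = NA_integer_) {
  structure(
    list(
      variant = match_variant(variant),
      coef = c(a = a, b = b, c = c, d = d),
      sigma = sigma,
      std_error = rep(NA_real_, 4),
      train_window = train_window,
      n_obs = n_obs,
      r_squared = NA_real_,
      scale = NULL,
      data = NULL
    ),
    class = "ibex_fit"
  )
}

#' @export
print.ibex_fit <- function(x, ...) {
  cat(sprintf("<ibex_fit> variant %s, trained %s-%s on %s growth years\n",
              x$variant, x$train_window[1], x$train_window[2], x$n_obs))
  cat(sprintf("  r = a + b*%s + c*P + d*%s*P + eps,  eps ~ N(0, sigma^2)\n",
              if (x$variant == "D1") "N" else "ln N",
              if (x$variant == "D1") "N" else "ln N"))
  print(round(x$coef, 6))
  cat(sprintf("  sigma = %.4f   R^2 = %.3f\n", x$sigma, x$r_squared))
  invisible(x)
}

#' Tidy a fitted growth model
#'
#' @param x An `ibex_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model term (`intercept`, `density`,
#'   `precip`, `density_precip`) and columns `term`, `estimate`,
#'   `std.error`.
#' @method tidy ibex_fit
#' @export
tidy.ibex_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "density", "precip", "density_precip"),
    estimate = unname(x$coef),
    std.error = unname(x$std_error)
  )
}

#' One-row summary of a fitted growth model
#'
#' @param x An `ibex_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `variant`, `sigma`, `r.squared`, `n_obs`,
#'   `train_start`, `train_end`.
#' @method glance ibex_fit
#' @export
glance.ibex_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    sigma = x$sigma,
    r.squared = x$r_squared,
    n_obs = x$n_obs,
    train_start = x$train_window[1],
    train_end = x$train_window[2]
  )
}
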