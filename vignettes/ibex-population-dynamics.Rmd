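---
title: "Modelling census dynamics with density and winter climate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling census dynamics with density and winter climate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibexdyn)
library(dplyr)
```

## The model

ibexdyn works with annual census counts $N_t$ of a closed ungulate
population (the motivating case is the Alpine ibex colony of a protected
massif, surveyed once or twice a year by park wardens) and winter
precipitation totals $P_t$, where "winter" is November through April and
each total is attributed to the calendar year it ends in. The state
variable of the model is the log growth rate

$$ r_t = \ln\frac{N_t}{N_{t-1}}, $$

attributed to the later year: the winter ending in year $t$ forces the
growth from the count taken in year $t-1$ to the count taken in year $t$.
The source censuses do not state this alignment; we fix it once, here, and
use it everywhere.

The growth rate is modelled as a linear function of the previous year's
density, the winter precipitation, and their product:

$$ r_t = a + b\,D_{t-1} + c\,P_t + d\,D_{t-1}P_t + \varepsilon_t,
   \qquad \varepsilon_t \sim \mathcal N(0, \sigma^2), $$

with two variants for the density covariate: **D1** uses the raw count,
$D = N$, and **D2** its natural logarithm, $D = \ln N$ (a stochastic
Gompertz model with climate forcing). The park area is constant over the
study period, so the count is proportional to density and no areal
normalisation is applied. The interaction term lets a harsh winter
intensify density dependence — deep, persistent snow makes forage scarce
exactly when intraspecific competition is strongest. Precipitation is a
proxy for snow depth; at high altitude and historical (pre-warming)
temperatures, winter precipitation falls overwhelmingly as snow, and
`proxy_correlation()` exists to quantify, on any pair of overlapping
series, how good such a proxy is.

### What the package assumes and what it reconstructs

The functional family above is stated by its originators only in outline
("simple stochastic models" with density, precipitation and the product).
The estimator, the noise law and any covariate standardisation are **not**
published, so this package fixes them as explicit reconstructions:

* **Estimation** is ordinary least squares of $r_t$ on the four design
  columns, solved by QR decomposition. The residual standard deviation
  uses the $n - 4$ denominator and becomes the process-noise scale
  $\sigma$.
* **Noise** is additive Gaussian on the log growth rate, i.i.d. across
  years and realizations. Nothing heavier-tailed is attempted: with at
  most a few dozen growth observations per window there is no power to
  distinguish alternatives.
* **No covariate standardisation** is applied by default, which keeps
  coefficients in interpretable units (per animal or per log-animal, per
  mm) and keeps the fit exactly comparable to a hand-coded
  normal-equations solve. `fit_model(scale_covariates = TRUE)` centres
  and scales the density and precipitation columns, stores the transform
  on the fitted object, and re-applies it during simulation; fitted
  dynamics are unchanged.

A fit requires at least 5 usable growth observations (one more than the
number of parameters); fewer is an error, not a warning. Rank-deficient
designs — e.g. constant precipitation, which makes the precipitation
column collinear with the intercept — raise an error naming the collinear
column rather than silently dropping it.

## Forecasting and the alarm bell

`simulate_ensemble()` iterates the fitted model forward from a launch
count, drawing fresh noise each year and each realization:

$$ N_{t+1} = N_t \exp\!\big(a + bD_t + cP_{t+1} + dD_tP_{t+1} +
   \varepsilon\big). $$

Counts are kept continuous throughout (rounding a few-thousand-head count
would inject spurious drift at low numbers); they are rounded only when a
report is serialised, and then both raw and rounded columns are written.
A count below 1 animal is absorbed at 0: extinction is a state, and an
extinct realization stays extinct.

The default protocol is **1000 realizations** summarised by the per-year
ensemble mean and the **90% empirical band**, i.e. the per-year 5% and
95% quantiles computed by linear interpolation of order statistics
(`stats::quantile` type 7, recorded in the output metadata). With 1000
realizations this guarantees at least 900 realizations inside the closed
band each year and at most 50 strictly below the lower edge — a
bookkeeping property the test suite checks directly.

`validate_out_of_sample()` compares later observed counts against the
band. The closed interval is used deliberately: a tie at the band edge
counts as inside, so a zero-noise model can never raise a false alarm on
its own mean trajectory. The earliest validated year outside the band —
`first_band_exit()` — is the protocol's *alarm bell*: up to that year,
density and climate suffice to explain the record; from it onwards, other
causes (management change, poaching, war) must be invoked. The package
reports the exit year together with the sign of the ensemble-mean trend
over the forecast window (`glance()` on a windowed experiment), because a
divergence claim rests on both: observations leaving the band, and the
predicted trend pointing the other way.

Windowed experiments (`run_windowed()`) fit on the census up to a chosen
year and validate against everything later, mirroring the standard
calibrate-on-the-first-20-years / validate-on-the-rest design. A fit
window that ends at the last observation yields an empty forecast and an
empty report — a degenerate case, not an error.

## The synthetic-data generator

No archival census or weather series is shipped; every analysis is
exercised on synthetic data whose defaults (`scenario_spec()`) are this
package's calibration choices, fixed once:

* **True model** (D2): $a = 1.104$, $b = -0.12$, $c = -8\times10^{-4}$,
  $d = 6.7\times10^{-5}$, $\sigma = 0.07$. Under the mean climate this
  gives an equilibrium near 3900 animals and ~4.5% annual growth at a
  count of 2370 — a colony rising from 2370 toward ~3900 over a decade,
  the regime of the motivating interwar record. The precipitation effect
  is negative at all realistic densities (snowy winters depress growth).
* **Climate**: i.i.d. truncated-at-zero Gaussian Nov–Apr totals with mean
  450 mm and sd 120 mm, the order of magnitude of alpine valley-floor
  winter totals with strong year-to-year alternation. Winters are
  exchangeable: no autocorrelation model, because the analysis treats
  them as exchangeable too.
* **Initial count** 2370 (founder mode: 25, a typical reintroduction
  nucleus), **20 years** by default.

Three optional features emulate the historical record's pathologies:
a **missing-year gap** (rows deleted from the observed output only — the
latent trajectory is intact, and growth pairs spanning the gap are
dropped, never interpolated); a **founder scenario** (low initial density,
near-exponential growth, the regime of a reintroduced colony far below
carrying capacity); and a **removal intervention**. Removal is modelled
as a survival fraction compounding on the reported count from the
changepoint year on: $k$ years into the intervention the observed count
equals the latent count times $(1-\text{rate})^k$, with the changepoint
year counting as the first removal year. The factor does not feed back
into the next year's density — the closed form keeps the intervention
exactly characterised and the detection experiment interpretable; a
feedback variant would let density-dependent compensation partially
offset the removal and would have no closed form. One-off emigration
pulses are deliberately not modelled.

What the generator does **not** emulate: observation error in the counts
(censuses enter the model as truth), count-method changes over time,
weather autocorrelation, age/sex structure, and one-off shocks. Passing
tests therefore demonstrate that the *protocol* behaves as designed under
its own assumptions — not that any historical series satisfies those
assumptions.

## Reproducibility and numerical choices

All randomness flows from one integer seed. Each consumer (climate,
census noise, warden jitter, each replicate of a study, each ensemble)
takes a child seed at a fixed offset via `child_seed()`, so any figure,
file or study is reproducible from the master seed alone; two CLI runs
with the same configuration are byte-identical. Ensembles restore the
caller's RNG state (`withr::with_seed`). The one-step update computes its
linear predictor elementwise rather than by matrix-vector product, so
identical states give bit-identical updates independent of their position
in the state vector — this is what makes the degenerate $\sigma = 0$
ensemble exactly degenerate.

## Study sizes

The package's Monte-Carlo studies (exported as `study_*()` and rerun by
both the test suite and `scripts/acceptance.R`) use: 1000-realization
ensembles over 15 forecast years for band bookkeeping and coverage
(coverage averaged over 500 replicate observation trajectories drawn from
the same model); 500 replicate refits at 50 and 100 years for consistency
of the estimator; and 200 replicates per removal strength
$\{5\%, 10\%, 20\%\}$ for the detection study, with a 20-year calibration
window, the changepoint in the first forecast year, and a detection
window of changepoint $+3$ years. These sizes give Monte-Carlo standard
errors comfortably below the margins being checked (e.g. ~0.002 on a
coverage of 0.9 averaged over 500 × 15 year-flags) while a full run of
every study completes in about a minute.

## Known limitations

* Coefficients of the interwar-style design are strongly collinear
  (density and density × precipitation share most of their variance), so
  individual coefficients from a 20-year window carry large standard
  errors even when the fitted *dynamics* are well constrained. The
  parameter-recovery study shows consistency, not short-window precision;
  forecasts from a refitted (rather than true) model inherit this
  estimation error, and their bands — which carry process noise only, not
  parameter uncertainty — are accordingly anti-conservative over long
  horizons.
* A series with essentially one rising trend and one falling trend
  carries little information about density dependence; the model is most
  informative as an alarm bell, not as a parameter-measurement device.
* The band is pointwise per year, not simultaneous across years; over a
  15-year horizon the family-wise chance of at least one spurious exit is
  well above 10%, which is why detection claims are framed as "exit
  within a few years of the changepoint" rather than "any exit".
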