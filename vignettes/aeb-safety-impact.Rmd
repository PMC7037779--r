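---
title: "Methods: modelling the national safety impact of automatic emergency braking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the national safety impact of automatic emergency braking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aebimpact` estimates how many road-traffic fatalities and severe injuries
automatic emergency braking (AEB) avoids each year at national scale. The
core identity multiplies five ingredients per casualty kind *k* and year
*y*:

```
SI_k,y = CN_k,y · |EC_k| · PS_k · PW_k · PL_k · PO · PR_y
```

a no-AEB casualty forecast `CN`, the full-penetration effectiveness `EC`,
the technical limiting factors (speed `PS`, weather `PW`, light `PL`,
activation `PO` — applied only in the realistic, "pessimistic" scenario),
and the fleet penetration rate `PR`. This vignette records the modelling
assumptions, the defaults and why they were chosen, and what the synthetic
data generator can and cannot stand in for.

## Casualty forecasting: GM(1,1) with Markov residual correction

National casualty series are short (about ten usable annual observations),
strictly positive, and decline quasi-exponentially — conditions under
which grey models are the standard tool. `fit_gm11()` accumulates the raw
series (`x1 = cumsum(x0)`), forms the trapezoid background
`z1(k) = 0.5 (x1(k) + x1(k-1))`, and solves the whitened equation
`x0(k) + a·z1(k) = b` by least squares over `k = 2..n`. The fit requires
at least four observations; a constant series drives the development
coefficient `a` to zero and is rejected as degenerate rather than silently
returning a non-exponential model.

**Prediction uses the discrete solution of the grey difference equation**,
with annual ratio `β = (1 − a/2)/(1 + a/2)`, not the continuous-time
response `e^(−a·k)` that much of the grey literature prints. The two agree
to second order in `a`, but only the discrete solution reproduces an
exactly geometric series with zero error — a property the test suite pins
at `1e-9` — and only under it does "the fitted model of geometric data"
mean "the same geometric progression". For the decay rates relevant here
(`a ≈ 0.03`) the numerical difference is a few parts in 10^5 per step.

The Markov layer partitions relative residuals
`ε_k = (observed − fitted)/fitted` into `n_states` equal-width intervals
spanning the residual range and counts transitions between consecutive
years. Conventions:

* **Residual sign.** The correction multiplies a forecast by `(1 + c)`
  with `c` a state centre, so residuals are oriented
  observed-relative-to-fit; the diagnostic columns (`relative_error`,
  reported as `(fitted − observed)/observed`) keep the opposite,
  error-of-the-fit orientation that accuracy tables conventionally use.
* **Default `n_states = 3`.** With eight or nine usable residuals, three
  states keep at least two observations per state in typical draws; more
  states mostly produce empty rows. Configurable everywhere it appears.
* **Rows with no observed transitions are uniform**, keeping the matrix
  stochastic without asserting information the data lack.
* **Multi-step correction** propagates the last observed state's
  indicator vector `h` steps through the transition matrix and applies
  the probability-weighted mean of state centres. The weighted mean was
  preferred over the most-probable-state rule because it varies smoothly
  with the estimated probabilities and converges to the stationary
  correction instead of oscillating when two states tie.
* **Degenerate residuals** (all identical, e.g. a perfect fit) collapse
  to a single state whose centre is the common residual; the correction
  then equals plain GM(1,1) when that residual is zero.

In-sample, each year's fitted value is scaled by the centre of the state
its own residual occupies; since the centre is within half an interval
width of the residual, this can only shrink the absolute relative error —
the suite checks the corrected mean absolute relative error never exceeds
the uncorrected one.

## Full-penetration effectiveness

`EC` composes two safety mechanisms: the direct effect
`EC_m1 = Σ_i EC_i·PC_i` weighting per-collision-type effectiveness by the
share of casualties in that type, and a small indirect behavioural term
`EC_m3 = +0.3%`, composed multiplicatively:
`EC = (1 + EC_m1)(1 + EC_m3) − 1`. Reductions are encoded as *negative*
fractions so that composition needs no sign gymnastics; every report shows
the magnitude.

Four collision types carry non-zero effectiveness: pedestrian and
road-obstacle collisions (fatalities −44%, injuries −33%; the obstacle
value is taken equal to the pedestrian value), rear-end collisions (−43%),
and head-on collisions (−27%, the front-impact estimate — the literature
does not label a head-on-specific value, so the front-impact figure is the
defensible default and is configurable like every other entry). Sideswipe,
angle, roadside-single-vehicle and residual categories contribute zero.

The packaged 2017 Chinese table carries a subtlety: the nine listed
collision types do not exhaust the printed totals (their fatality counts
sum to 63,322 against a total of 63,772), and the published per-type
percentages are denominated on the totals. `collision_type_table()`
therefore computes proportions against the total row when one is present
and cross-checks them against the printed percentages to 0.01 percentage
points, failing loudly with the offending row otherwise.

## Limiting factors

The realistic scenario multiplies four fractions, each estimated from the
2017 condition-distribution table:

* **Speed `PS`.** AEB is treated as effective below 60 km/h. Speed is not
  recorded in the source statistics, so the engaged transmission gear
  proxies it: gears 1–4 or reverse count as below 60 km/h, gear ≥ 5 as
  above. Automatic-transmission, neutral and unclear-gear collisions are
  excluded from numerator and denominator alike — speed is unobservable
  there, and the retained manual-in-gear subsample is assumed
  representative. This yields 63.0% for fatalities and 70.4% for
  injuries. (The injury computation must include reverse gear and the
  34.35% unclear share from the distribution table; dropping either does
  not reproduce the published 70.38%.)
* **Light `PL` = 1 − (night without streetlights).** Dusk and dawn count
  as workable light, consistent with the published 75.58%/85.51%.
* **Weather `PW` = sunny + cloudy** (88.36%/88.82%); rain, snow, fog and
  the rarer categories are outside the operating envelope.
* **Activation `PO` = 0.93**, the observed share of drivers leaving
  forward-collision warning/AEB switched on.

Factor-level assertions use tolerances of 0.05–0.1 percentage points
because the source columns are printed to two decimals; the factors are
recomputed from those rounded proportions, not from microdata.

## Fleet penetration

Vehicle ownership per 1000 people follows the Gompertz curve
`VO = VOS·exp(α·exp(β·PGDP))` with saturation `VOS = 376` and constants
`α = −3.3546`, `β = −0.00013` (fitted to 2017–2018 data; `β`'s scale
implies per-capita GDP in US-dollar-sized units, and the packaged base
value 9,770 at 2018 follows suit). Per-capita GDP compounds annual growth
rates linearly interpolated between anchors (6% in 2020 declining to 2%
in 2050; the generator adds a 2018 anchor so the compounding can start at
its base year — no extrapolation outside the anchor span is permitted).

New-vehicle sales solve the stock balance
`NV_y = VO_y·Pop_y/1000 − Σ_{t=1..18} SR_t·NV_{y−t}` sequentially; a
negative balance is floored at zero with a warning. Fleet penetration is
then computed from **cumulative surviving equipped cohorts**,

```
PR_y = Σ_{t=0..18} NPR_{y−t} · NV_{y−t} · SR_t / (VO_y·Pop_y/1000)
```

with `SR_0 = 1`, clamped to `[0, 1]`. A single-year form (`NPR_y·NV_y`
over the stock) cannot produce a cumulative fleet share — one year's
sales are an order of magnitude smaller than the stock — so the cohort
sum is the only formulation consistent with a penetration trajectory that
reaches tens of percent. Years older than the sales history contribute
nothing *only because* their scheduled `NPR` is zero; a positive `NPR`
with missing sales is an error, not a silent zero.

## Scenarios and sensitivity

The baseline scenario applies no AEB effect; the optimistic scenario uses
`|EC|·PR_y`; the pessimistic one multiplies in the combined factor
product. Two identities are enforced rather than merely hoped for:
pessimistic avoided = optimistic avoided × combined adjustment, exactly,
every year; and the single-factor uplifts `1/f − 1` jointly multiply back
to the optimistic/pessimistic ratio. Percent reductions are computed from
unrounded intermediates; casualty counts are kept as reals throughout and
rounded half-up to integers only when report CSVs are written.

## The synthetic-data generator

The national casualty series, the survival schedule and the historical
sales that feed the original analysis are not distributed with their
source yearbooks, so `synth_config()` generates statistically analogous
inputs:

* **Casualty series**: `x_k = base·(1 − d)^k·(1 + ε_k)`,
  `ε ~ N(0, cv²)`, defaults 63,000 fatalities / 210,000 severe injuries
  at 2008, `d = 3%`/yr, `cv = 1%`, ten years. Noise is multiplicative
  because grey models assume a quasi-exponential trend and additive noise
  would eventually violate positivity; non-positive draws are resampled.
  The defaults place the series at the magnitudes of the Chinese
  2008–2017 statistics so fixture outputs are visually comparable.
* **Fleet fixture**: population rising to a 1.463-billion plateau in
  2030; the Gompertz/GDP parameters above; a logistic survival curve
  `S(t) = 1/(1 + exp(0.6·(t − 16)))` truncated at 18 years; and an
  18-year sales history growing 8%/yr, scaled so the first projected
  sales year continues the historical ramp smoothly. The survival
  midpoint of 16 (≈15-year mean service life) was chosen because it is
  consistent with an 18-year maximum vehicle age and, together with the
  policy schedule, puts the fleet-penetration trajectory in the
  neighbourhood of the published 10.4%/34.0%/60.3% checkpoints
  (2020/2025/2030); a midpoint near 11 (≈10-year life) turns the fleet
  over implausibly fast and overshoots all three. The checkpoints are
  asserted loosely (±5 percentage points) precisely because the true
  survival and sales inputs are unavailable.
* **Condition log**: per casualty kind, `n` records with gear, light and
  weather drawn independently from the generating shares (default: the
  packaged 2017 table). Empirical factor estimates converge to the
  generating values at the usual `n^(−1/2)` rate; tests use 10^6 draws
  for tight (±0.5 pp) checks and 10^3 for sampling-error bounds.

Everything is deterministic given the configuration seed; fatality and
injury streams use distinct derived substreams.

What the generator does **not** emulate: structural breaks (reporting
changes, pandemic years, policy shocks) in the casualty series;
correlation between gear, light and weather within a collision; cohort- or
segment-dependent survival; provincial heterogeneity; and any feedback of
AEB adoption onto exposure. Passing tests therefore demonstrate that the
pipeline's arithmetic and statistical machinery behave as specified on
data with the assumed structure — not that the grey model is an adequate
description of any particular country's future.

## Problem sizes and numerical choices

The test suite fits ten-year series, uses 20 seeded replicates for the
decay-recovery and transition-matrix property checks, 13-year forecast
horizons, and condition logs up to 10^6 records — sizes chosen so the
whole suite completes in well under a minute while leaving the sampling
error of each check an order of magnitude below its assertion tolerance.
Degenerate inputs are handled explicitly rather than numerically:
constant series, identical residuals, empty transition rows, zero stock
denominators and negative stock balances each have a defined behaviour
documented on the function.

## Limitations

* Percent reductions are exact algebra; avoided *counts* inherit all the
  uncertainty of the casualty forecast, for which the grey model provides
  no distributional statement.
* The gear-as-speed proxy assumes manual-gear collisions represent the
  speed mix of all collisions.
* Effectiveness constants are point estimates imported from studies in
  other driving environments; the package treats them as configuration,
  not as estimands.
* The framework generalises to other driver-assistance functions only by
  supplying their per-type effectiveness and applicability factors; no
  other function is parameterised here.
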