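---
title: "Methods: soil CO2 efflux modelling and post-disturbance carbon budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil CO2 efflux modelling and post-disturbance carbon budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxbudget)
```

# The problem

When a forest section is cleared by wind, beetles or harvest, its carbon
balance is governed by a race between regrowing vegetation (carbon in) and
soil organic-matter decomposition (carbon out). `fluxbudget` assembles a
plot-scale net ecosystem productivity (NEP) budget for such sections from
chamber soil-respiration surveys, continuous soil-temperature records,
root-exclusion experiments and biomass harvests — the standard ground-based
alternative where no flux tower is available.

# Models and procedures

## Chamber flux

A closed chamber on a soil collar accumulates CO2; the efflux is inferred
from the headspace concentration rise. We fit a quadratic
$c(t) = a_0 + b_1 t + c_2 t^2$ and convert the *initial* rise rate $b_1$
(ppm s^-1^) to a molar flux

$$F = b_1 \, \frac{P}{R\,T} \, \frac{V}{A} \quad [\mu mol\; CO_2\; m^{-2} s^{-1}],$$

with chamber system volume $V$, collar footprint $A$ and the molar density
of air from the ideal gas law. Taking the derivative at $t=0$ rather than a
mean slope matters: as CO2 accumulates, the soil–headspace gradient
flattens and the trace saturates. The curvature term absorbs that
saturation, so the quadratic fit recovers the true flux exactly on
noiseless saturating traces where a straight-line fit is biased low (this
is a test in the suite). Negative fluxes (uptake) are passed through
unclamped.

Defaults: collar diameter 0.10 m; system volume 1.17 L (typical for
portable-IRGA survey chambers — instrument headspace volumes are rarely
reported, so this is a documented, overridable default, not a measured
value); air pressure from the standard-atmosphere formula at 950 m
elevation (≈90.4 kPa) when unmeasured. QC screens traces for a minimum of
4 points (one more than a quadratic needs) and a plausible starting
concentration (450 ± 150 ppm by default); a non-increasing trend is flagged
but not rejected.

## Temperature response and annual upscaling

Each plot's seasonal flux course is summarised by the exponential model

$$R_s = F_{10} \, Q_{10}^{(T-10)/10},$$

fitted by Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`), which is the fitting route practitioners use for
this model. Start values are $F_{10} = \bar{R_s}$ and $Q_{10} = 2$; bounds
$F_{10} > 0$, $Q_{10} \in (0.5, 10)$ prevent pathological exponents on
noisy plots without constraining realistic fits (forest soils typically
show $Q_{10}$ 2–4). Fits use the soil temperature measured manually during
each campaign, not logger readings, mirroring the field protocol. $R^2$
may be negative for bad fits and is stored as-is.

Annual totals come from evaluating the fitted model at every 3-hourly
logger timestamp and holding each value constant over its interval
(left-constant weighting, 365-day year). Replicate loggers are averaged
per timestamp; gaps up to 24 h are bridged linearly, longer gaps count as
uncovered, and cumulation aborts below 95% coverage. A single reading
never represents more than 24 h (otherwise a truncated series would
silently claim the rest of the year). Against a 1-minute numerical
integration of an analytic sinusoidal year, the 3-hourly left-constant sum
agrees within 0.2%; the discretisation error is negligible because the
annual sinusoid varies slowly relative to 3 h.

Unit bridge: 1 µmol CO2 m^-2^ s^-1^ sustained for 365 days is
3.788 t C ha^-1^ (12.011 g C mol^-1^).

## Partitioning soil respiration

Total efflux $R_s = R_a + R_h$ splits into autotrophic (roots and
rhizosphere) and heterotrophic (decomposition) components:

* **Trenching** severs roots around a plot, so trenched efflux ≈ $R_h$.
  The autotrophic percentage is the per-campaign reduction
  $100(1 - \text{treated}/\text{control})$, averaged with equal campaign
  weights (a flux-weighted mean is available behind a flag). Campaign-level
  reductions are not clamped — noise can make single campaigns negative —
  but the final estimate is clipped to [0, 100] with a warning.
* **Clipping** removes aboveground ground vegetation repeatedly, starving
  roots of fresh assimilates. Because clipped vegetation resprouts, the
  treated/control difference only stabilises late in the season; the
  estimator therefore uses campaigns at/after a stabilization date
  (default 1 September of the study year — "autumn" — and deliberately an
  explicit config item for real runs). The result is a conservative
  (lower-bound) $R_a$ estimate; no resprouting correction exists and none
  is applied.
* **Fine-root scaling** transfers a measured fraction between sections in
  proportion to their fine-root carbon stocks (0–10 cm):
  $a_{target} = a_{ref} \cdot f_{target} / f_{ref}$. The stock ratio is
  unit-free; the rationale is that root-derived respiration scales with
  standing fine-root biomass when vegetation type is comparable.

Fractions are estimated from measured campaign fluxes and then applied to
the modelled annual totals ($R_a = R_s \cdot a/100$, $R_h$ the exact
complement) — a two-step procedure; conservation $R_a + R_h = R_s$ is
exact before rounding and asserted in tests.

## Litter inputs and NEP

Herb-layer standing biomass at the end of the growing season is taken 1:1
as the annual aboveground ground-vegetation litter input (a known
conservative assumption), converted at 47.5% C of dry weight; tree
litterfall from collector catches at 50% C; belowground litter as
fine-root stock × turnover (0.8 yr^-1^). Then

$$NEP = \Delta B + L_{tree} + L_{herb} + L_{root} - R_h,$$

positive = sink. For clearings $\Delta B$ and $L_{tree}$ are structurally
zero (NEP reduces to litter input minus $R_h$). The biomass increment of a
forested section enters as an input scalar: deriving it from inventory
belongs to mensuration, not to this pipeline. Budget closure
($NEP + R_h - \Delta B - \sum L = 0$) is exact; rounding to one decimal
(round-half-even) happens only in the report formatter, never inside
computation.

# The synthetic-study generator

`simulate_study()` emulates the field design so every estimator can be
validated against known truth: three sections × 12 plots, campaigns every
21 days in a March–November snow-free window, 4 replicate loggers per
section at 3-h resolution over one year, trenching pairs in the mature
stand and clipping pairs in the vegetated clearing, 6 herb frames and 12
root cores per section.

Generator choices, made once:

* Soil temperature = annual sinusoid (mean 8.2 °C, amplitude 7.5 °C, peak
  mid-July) + damped diurnal sinusoid (1 °C, peak 14:00) + Gaussian noise
  (0.8 °C). These magnitudes are typical of montane soils at ~950 m with a
  long snow-free season.
* Flux noise is multiplicative lognormal with mean 1, parameterised by its
  CV — fluxes are positive and their scatter grows with the mean. The
  default campaign CV is 0.2, chosen so that per-plot fits on synthetic
  data show $R^2$ in the high-0.7s to high-0.8s, the range seasonal
  chamber surveys typically report; benchmark tests that specify their own
  noise level (e.g. 10% CV for parameter recovery) pass it explicitly.
* Treatment pairs: the ground-truth autotrophic fraction is imposed as a
  fraction of total efflux (constant for trenching; a linear ramp reaching
  the plateau at the stabilization date for clipping). This is not a
  mechanistic root-respiration model, but it is exactly what the
  estimators claim to measure, so it is the right closed-loop target.
  Pair-level noise defaults to CV 0.05 since campaign means over 12 plots
  are much less noisy than single chambers.
* The bundled scenario triple (`default_study_scenarios()`) reproduces the
  magnitudes observed in montane spruce chronosequence studies: annual
  $R_s$ ≈ 8.9/8.5/8.9 t C ha^-1^ (per-plot $F_{10}$ calibrated by
  inverting the annual cumulation under the noise-free climate, which is
  exact because the total is proportional to $F_{10}$), $Q_{10}$ = 3.0 ±
  0.4, autotrophic fractions 44/18/35%, herb stocks 0.32/1.16/2.26 and
  fine-root stocks 1.56/0.40/0.79 t C ha^-1^, tree litterfall 1.8 and
  biomass increment 3.8 t C ha^-1^ yr^-1^ in the mature stand.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: snowpack and soil-freezing dynamics, moisture
limitation of respiration (the sites in question were never
moisture-limited, so none is modelled), spatial autocorrelation between
plots, root decomposition in trenched plots, and instrument drift. The
closed-loop results certify the estimators, not the field protocol.

# Numerical choices and degenerate inputs

* Quadratic fits: ordinary `lm`; fewer than 4 samples or fewer than 3
  distinct times is an error. Exact-polynomial traces are recovered to
  1e-9.
* Q10 fits: all-equal temperatures → unidentifiable error; optimizer
  failure returns a fit flagged `converged = FALSE` rather than aborting a
  whole section.
* Cumulation is exactly linear in $F_{10}$ and reduces to the closed form
  `flux_to_annual_units(f10, year)` for $Q_{10} = 1$ or constant 10 °C —
  both used as test anchors.
* Partition estimates outside [0, 100]% are clipped with a warning (noisy
  pairs can produce them); inside computation nothing is rounded.
* Campaign-weighted vs flux-weighted reduction means are both available;
  campaign weighting is the default because the field statistic of record
  is "average percent reduction across campaigns".

# Problem sizes used in the test suite

Closed-loop benchmarks run at: 1000 noisy chamber traces (flux recovery),
200 plots × 12 campaigns at 10% CV (median $|F_{10}|$ error < 3%,
$|Q_{10}|$ error < 8%), 200 seeds for each partition estimator (recovery
within 2 percentage points), and 100 full study seeds for the NEP-ordering
property (mature stand > older clearing > younger clearing in ≥95% of
seeds). These sizes give stable Monte-Carlo estimates while keeping the
suite under a minute on one core.

# Known limitations

* The exponential model slightly misfits at the flux extremes (a known
  property of single-predictor $Q_{10}$ models); no bias correction is
  applied.
* Whether the cumulation year is a calendar year or a logger year is a
  config decision (`cumulation$period`); the default is the logger span.
* No DOC/DIC leaching term, no soil C stock-change bookkeeping, no
  uncertainty propagation beyond per-component SD/SE.
* Clipping yields a lower bound on $R_a$; budgets built on it overstate
  carbon losses from vegetated clearings accordingly.
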