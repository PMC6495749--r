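---
title: "Methods: growth kinetics and carbon-isotope fractionation of hydrogenotrophic methanogens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth kinetics and carbon-isotope fractionation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanofrac)
```

## What the package models

`methanofrac` analyzes the physiology of hydrogenotrophic methanogens
(archaea reducing CO₂ to CH₄ with H₂, 4 H₂ + CO₂ → CH₄ + 2 H₂O) grown
under varying H₂ supply: in a sparged chemostat, in sealed serum bottles
with an H₂ headspace, and in coculture with a fermentative heterotroph
that supplies H₂ by interspecies transfer. Three strands of quantitative
analysis are covered:

1. **Growth and production kinetics** — specific growth rate *k*, cell
   yield *Y* (cells per mol product), and cell-specific production rate
   *q* (fmol cell⁻¹ h⁻¹).
2. **Headspace gas chemistry** — isochoric pressure scaling, ideal-gas
   amounts, and Henry's-law aqueous concentrations.
3. **Carbon-isotope fractionation** — δ¹³C systematics of the CO₂ → CH₄
   conversion, including a closed-system Rayleigh drawdown model and its
   inversion.

A seeded synthetic-data generator (`gen_*` functions) reproduces the
statistical structure each estimator assumes, so the entire pipeline is
testable without any laboratory data.

## Growth and production kinetics

**Growth rate.** `fit_growth_rate()` is ordinary least squares of
ln(count) on time: exponential growth `x(t) = x₀·e^{kt}` is linear in log
space with slope *k* (h⁻¹). Counts must be strictly positive; non-positive
values are rejected rather than dropped, because silently discarding
points changes the estimate. The fitting window is explicit
(user-supplied indices, default all points): selecting the log-linear
phase is a scientific judgement that should be visible in the call, not
hidden in a heuristic.

**Chemostat rates and yields.** At steady state, CH₄ leaves a sparged
reactor by two routes, so the vessel-total production rate is

> rate = [CH₄]ₕₑₐdₛₚₐcₑ · F_gas + [CH₄]_dissolved · (D · V)

with D the dilution rate (h⁻¹), V the liquid volume (l) and F_gas the gas
outflow (l h⁻¹). `chemostat_production_rate()` normalizes by the cells in
the vessel (X·V·10³ for X in cells ml⁻¹) to give *q*; a `cells_basis =
"per_ml"` alternative normalizes by X alone, since reports are ambiguous
about which normalization a given study used. `chemostat_yield()` divides
the cell production rate D·X·V·10³ by the CH₄ production rate; the
identity **Y · q = D** (q in mol cell⁻¹ h⁻¹) holds algebraically for every
operating point and is asserted in the tests.

**Batch yields and rates.** In a sealed bottle, `batch_yield()` regresses
cells against cumulative product; the slope is Y in cells mol⁻¹. The
intercept is kept free by default because bottles start with a nonzero
inoculum — forcing the line through the origin biases the slope whenever
the inoculum is appreciable (a through-origin mode exists behind a flag).
The cell-specific rate follows the doubling-time formula

> q = k / (ln 2 · Y),

implemented with `ln 2` at full precision (printed forms of this formula
round it to 0.693). Note the non-commutation of averaging: applying the
formula to condition-mean k and Y does not equal the mean of
per-replicate q values. The pipeline therefore computes per-replicate
estimates first and aggregates as mean ± standard error
(`run_condition()`), which is how per-condition summaries with error bars
must be produced.

## Gas chemistry

Sealed bottles are filled at room temperature and incubated hot at fixed
volume, so the pressure scales as P₂ = P₁·T₂/T₁. We fix "room
temperature" at 23 °C (296.15 K): any fill temperature in the 20–25 °C
range reproduces a 1.2 atm total pressure at 82 °C to one decimal, but
23 °C also reproduces the 1.92 atm H₂ partial pressure of a 2-atm 80:20
H₂:CO₂ fill at two decimals, so it is the convention used throughout the
examples and tests. Ideal-gas behavior is assumed everywhere (pressures
≤ 2.4 atm, temperatures ≥ 295 K; compressibility corrections are below
1%).

Aqueous concentrations come from Henry's law with a van 't Hoff
temperature correction, `c = p · kH(T_ref) · exp(B·(1/T − 1/T_ref))`,
with shipped freshwater constants for H₂ (7.8×10⁻⁴ mol l⁻¹ atm⁻¹ at
298.15 K, B = 500 K), CH₄ and CO₂. No salinity (Setschenow) correction
and no activity coefficients are applied: this is a deliberate
simplification relative to full geochemical speciation software, and it
is why aqueous estimates for seawater-like media carry roughly 10%
uncertainty. `sparge_partial_pressure()` converts feed-gas flow rates to
mole fractions for an open reactor at ambient pressure.

## Carbon-isotope systematics

δ¹³C is the per-mille deviation of a sample's ¹³C/¹²C ratio from VPDB
(R_std = 0.0112372). The fractionation factor between substrate and
product is

> α = R_CO₂ / R_CH₄ = (δ¹³C_CO₂ + 1000) / (δ¹³C_CH₄ + 1000),
> ε = (α − 1)·1000 ‰,

computed by `alpha_epsilon()`. Measurement uncertainty propagates to ε by
first-order quadrature (`propagate_epsilon_uncertainty()`); with the
typical 0.3‰ injection SD on both deltas this gives ≈0.46‰ at chemostat
conditions.

**DIC → CO₂(aq).** IRMS measures the dissolved inorganic carbon pool, but
the substrate of methanogenesis is CO₂(aq). `dic_to_co2()` applies the
temperature-dependent equilibrium fractionation between CO₂(aq) and
HCO₃⁻, ε(T) = −9866/T + 24.12 ‰ (Mook's classical constants, T in
kelvin; −3.66‰ at 82 °C). Near pH 6 and high temperature, DIC is
effectively bicarbonate, so the default treats the measured pool as pure
HCO₃⁻; supplying a pH partitions DIC between CO₂(aq) and HCO₃⁻ through
the first carbonic-acid dissociation constant before applying the
pairwise offset. The constant set is configurable (`mook_params()`)
because published formulations differ slightly.

**Rayleigh drawdown.** When a closed CO₂ pool is extensively consumed,
the residual reactant enriches and the final deltas no longer measure ε
directly. `rayleigh_forward()` simulates this: the reactant is removed in
`n_steps` equal log-spaced increments, each increment's product offset
from the instantaneous residual by the factor 1/α *in ratio space*.
Fractionation is applied in ratio space rather than as an additive ‰
offset because the additive approximation drifts noticeably once ε
exceeds ~50‰ — exactly the coculture regime. Ratios mix linearly (the
standard trace-isotope approximation), so isotope mass balance
f·δ_residual + (1−f)·δ_product = δ₀ holds exactly at every step; this is
asserted to 10⁻⁶‰ in the tests. The step size is a model choice, so the
implementation demonstrates convergence: the stepwise trajectory
approaches the closed-form Rayleigh solution
δ_residual = (δ₀+1000)·f^{(1/α)−1} − 1000 monotonically, agreeing within
0.01‰ by 10⁴ steps; the closed form (`method = "analytic"`,
`rayleigh_residual_delta()`) is retained as an independent oracle.

**Inversion.** `rayleigh_invert()` recovers (ε, f) from three measured
deltas. The two-unknown system decouples: f follows exactly from linear
mass balance, f = (δ₀ − δ_product)/(δ_residual − δ_product), and ε is
then a robust one-dimensional bracketed root solve (ε ∈ (0, 200]‰) on
the residual equation of the chosen forward model. The degenerate case
δ_residual = δ₀ returns ε = 0, f = 1; orderings inconsistent with
drawdown (residual not enriched, product not depleted) are errors.

For the extensively drawn-down monoculture bottles, the residual CO₂
entering the inversion is the **CO₂(aq)** value — the measured final DIC
converted through `dic_to_co2()` at 82 °C — not the raw DIC delta. Using
the DIC value directly inflates the recovered ε by about 1‰, which is the
main reason the two choices are kept as explicit, separate inputs.

## The synthetic-data generator

The generators define the study conditions the estimators are meant for
and are used for all round-trip testing:

- **Count noise** is multiplicative lognormal with unit mean (default
  CV 0.05): counts are positive and microscopy counting error is
  proportional to the count. The CV is a stand-in — counting error is
  rarely reported — and is exposed as a parameter.
- **Isotope noise** is additive Gaussian with SD 0.3‰, the typical
  injection-to-injection SD of IRMS measurements.
- **Chemostat runs** are constructed so that the total CH₄ production
  rate equals q·X·V·10³ exactly, partitioned 95:5 between the gas stream
  and the dissolved outflow (a sparged reactor strips nearly all CH₄ to
  the gas phase); the zero-noise construction is the exact inverse of the
  estimators.
- **Coculture bottles** use a quasi-steady mass-balance closure: the
  heterotroph grows exponentially, H₂ transfer is instantaneous, the
  standing H₂ pool is a small constant fraction (0.5%) of cumulative
  production, and CH₄ is ¼ of transferred H₂. No Monod kinetics, H₂
  inhibition, or dissolved-gas dynamics are modeled — the estimators
  under test are regression-based and do not require them. Per-cell rate
  parameters use the q = k/(ln 2·Y) convention so that generator →
  estimator round trips are exact identities.
- **Isotope drawdown** series follow the closed-form Rayleigh solution
  with log-spaced f observations.

Passing round-trip tests on these generators shows the estimators are
correct for data with this structure; it does **not** validate the
biological assumptions (true exponential growth, constant per-cell rates,
complete H₂ transfer, constant fractionation during drawdown) against
real cultures.

Default problem sizes keep the full suite fast: 8-point growth series,
10-point bottle series, three chemostat replicates per condition, 60–200
Monte-Carlo seeds for bias and scatter checks, and 10⁵-step Rayleigh
trajectories (the stepwise recursion has a closed solution per step, so
this costs microseconds).

## Numerical choices and degenerate inputs

- δ values are carried at full precision; rounding to one decimal happens
  only in formatted reports (`format_condition_summary()`).
- A flat count series gives a perfect constant fit; its r² is reported as
  1 (the constant model fits exactly) rather than NaN.
- Growth fits with fewer than 3 points, non-positive counts, all-zero
  product columns, zero production rates, and f outside (0, 1] are
  errors, not warnings.
- The root bracket for ε is (0, 200]‰, comfortably covering microbial
  methanogenesis (≲90‰); an unbracketed root is an explicit error.
- `uniroot` tolerance is 10⁻¹⁰‰, far below measurement uncertainty.

## Known limitations

- The Henry's-law module ignores salinity and non-ideality; aqueous
  concentrations in saline media are systematically high by up to ~10%.
- The DIC partitioning uses a freshwater pK₁ expression extrapolated to
  82 °C; at the default (pH-free) setting this only matters if DIC is
  not bicarbonate-dominated.
- One published per-condition table row (a maltose coculture bottle)
  prints an ε that differs from its own deltas by 0.1‰ — a rounding
  artifact in the source; the recomputed value is used in comparisons.
- The coculture generator cannot emulate diauxie, lag phases, H₂
  inhibition of the heterotroph, or formate switching; condition
  summaries for real bottles should always be inspected with
  `autoplot()` on the underlying fits.
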