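---
title: "Methods: climate-driven growth and dispersal of fall armyworm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-driven growth and dispersal of fall armyworm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fawspread simulates the population dynamics and spread of fall armyworm on
a regular grid at weekly timesteps, driven by gridded surface-temperature
and soil-dryness forcing. This vignette documents the model, its
parameters, and the design and numerical choices the package makes —
including the places where a published description leaves the design
genuinely open.

## Growth model

Within a cell, abundance `N` follows

\[ \frac{dN}{dt} = \Big(1 - \frac{N}{K}\Big)\,(r_p - r_n)\,N \]

with density dependence applied **only while the net rate is positive**;
declining populations fall as pure exponentials, unconstrained by `K`.
This asymmetry mirrors how the carrying capacity is introduced in the
underlying biology: `K` caps growth, it does not slow collapse.

Each weekly step uses the **closed-form logistic solution**
`K N e^{rt} / (K + N(e^{rt} - 1))` rather than explicit integration. At
weekly steps the net rate times the step length can reach |r|·dt ≈ 1.4,
where an Euler step would be visibly wrong; the closed form is exact for
constant within-step rates and unconditionally stable. The test suite
checks it against a fine-step (0.001-day) Euler integrator to within 0.1 %.

`K` defaults to 1e9 individuals per cell and is spatially uniform. Note a
bookkeeping quirk inherited from the source parameterisation: 1e9 per 9-km
cell is described there as "about 1 per m²", but an 81-km² cell has
8.1e7 m², so the stated density and the stated total differ by an order of
magnitude. We implement the stated total (1e9). The same rounding applies
to the Allee threshold θ = 10 000 per cell ("about 1 moth per ha";
arithmetically 1.23/ha). Both are configuration parameters, not constants.

## Thermal performance and its calibration

Positive growth `r_p(T)` uses the Schoolfield re-parameterisation of the
Sharpe–DeMichele reaction-kinetics model:

\[ r_p(T) \propto \frac{(T/T_{ref})\,e^{(H_A/R)(1/T_{ref} - 1/T)}}
   {1 + e^{(H_L/R)(1/T_L - 1/T)} + e^{(H_H/R)(1/T_H - 1/T)}} \]

(temperatures in Kelvin inside the formula; the package API is in °C).
The curve's absolute level is anchored at `r_p(27\ °C) = r_{ref}`, with
`r_ref` defaulting to 0.16/day — the midpoint of the 0.12–0.20/day range
measured across populations at 27 °C. The range, not a point estimate, is
what is published, so the package exposes `r_ref` as a parameter and takes
the midpoint as its default.

The source parameter set behind the fitted development-rate curve is not
published; what is published are three facts about the fitted curve: a
maximum at 33.5 °C, a value at 40 °C equal to 35 % of that maximum, and a
lower development threshold at 12.95 °C. `calibrate_thermal_response()`
therefore fits the five shape parameters (`HA`, `HL`, `TL`, `HH`, `TH`) to
those anchors by least squares (Nelder–Mead from a fixed starting point,
so the result is deterministic). Choices made here:

* **The lower threshold is treated as "≤ 2 % of peak", targeted at 1 %.**
  The functional form is strictly positive, so a literal zero is
  unattainable; 1 % keeps the fitted curve comfortably inside the 2 %
  bound without fighting the optimiser.
* **The fit is under-determined** (five parameters, three anchors). Any
  parameter vector satisfying the anchors is acceptable; determinism comes
  from the fixed start, not from identifiability. The shipped defaults in
  `thermal_response()` are one such calibrated vector, and the calibration
  is re-run and re-checked in the test suite.
* **Failure is loud**: if the optimiser cannot reach the anchors within
  tolerance (objective > `tol`), calibration stops with an error rather
  than returning a bad curve.
* We use a single growth-rate curve rescaled from the development-rate
  anchors. Development rate and intrinsic growth rate are distinct
  quantities conflated in the source description; rescaling the
  development curve through the 27 °C anchor is the parsimonious reading
  and keeps every printed fact true simultaneously.

## Stress mortality

Beyond each critical threshold, mortality scales linearly with exceedance
depth; survival over an exposure is `p = e^{-m a t}` with `a` the
accumulated stress units (°C·days for temperature, fraction·days for soil
dryness; sub-daily forcing integrates exceedance × Δt). Defaults
(`stress_params()`):

| stressor    | threshold        | mortality rate       |
|-------------|------------------|----------------------|
| cold        | CTmin = 12.97 °C | 0.2 /(°C day)        |
| heat        | CTmax = 39.8 °C  | 0.02 /(°C day)       |
| desiccation | Cwilting = 0.50  | 0.2 /day per unit    |

Two documented inconsistencies in the source values are resolved as
follows: the threshold text mentions 12.95 °C while the parameter table
and the worked survival example use 12.97 °C — we follow 12.97 (12.95
remains only the calibration anchor for the thermal curve's low end); and
the desiccation rate implied by "10 % daily mortality on dry soil" is
−ln(0.9)/0.5 ≈ 0.2107, but the printed value 0.2 is used.

Instantaneous net rates (`r_p − r_n`) evaluated at every forcing timestep
are averaged within calendar months (`monthly_rate_raster()`). The
arithmetic mean is the exactly right aggregate because growth compounds as
`exp((r_1 + … + r_n) t)`; the tests verify this product identity to
1e−12 relative error. A cell's **annual mean** rate classifies it:
strictly positive → permanent range; zero or negative → transient.
Mean-zero cells are deliberately classed transient (strict inequality):
a knife-edge population has no buffer against any perturbation.

## Short-range dispersal

The location kernel is the 2-D negative exponential `f(d) = e^{-d/α}`
with distances centre-to-centre Euclidean in cell units, truncated at
`dS = 2` cells (18 km) and discretised on the 5×5 neighbourhood. Two
interpretive choices:

* **The kernel argument is `d/α`, not `d·α`.** The published formula is
  typographically ambiguous, but the accompanying statement that `2α` is
  the mean dispersal distance identifies the standard radial exponential,
  whose mean displacement is `∫r²e^{-r/α}dr / ∫re^{-r/α}dr = 2α` (verified
  against numeric integration in the tests).
* **The leaving fraction is an explicit parameter, `p_disperse` (default
  1 %).** With α = 0.01 cells, the raw discretised kernel puts essentially
  all mass on the centre cell — by itself it cannot simultaneously satisfy
  "α = 0.01" and "1 % of the population disperses to adjacent cells".
  The package therefore normalises in two parts: the centre keeps
  `1 − p_disperse`, and the off-centre cells share `p_disperse` in
  proportion to their raw exponential weights (α shapes only the
  off-centre distribution). This preserves both published facts and is the
  module's main interpretive decision.

Raw off-centre weights are computed as `exp(-(d-1)/α)` — shifted by the
minimum off-centre distance — which is an exact renormalisation-invariant
rescaling that avoids floating-point underflow at small α.

Boundaries are **absorbing**: mass convolved off the grid or onto sea
cells is removed, on the argument that moths over ocean do not found
populations. On closed all-land domains the convolution conserves mass to
machine precision (tested), and the per-step loss is itemised in the mass
accounting.

## Long-range dispersal

Each week, every occupied cell sends a fraction β = 0.05 of its population
as **one packet** to **one destination drawn uniformly from the land cells
within 540 km** (60 cells at 9 km), origin excluded; if no destination is
eligible the migrants are lost. Design notes:

* Uniform-over-eligible-cells (rather than uniform direction × distance)
  matches a "randomly selected destination cell" reading and makes the
  destination distribution independent of discretisation artefacts.
* One packet per source per week is an explicit convention; splitting β·N
  across several destinations is equally consistent with the published
  description but interacts differently with the Allee threshold. The
  packet convention lets large sources found viable colonies, which is the
  mechanism the Allee threshold exists to gate.
* Eligible destination sets are precomputed once per land mask and reused
  across steps and replicates.
* Distances are planar; at 9-km cells and ≤540-km jumps the metric
  distortion is small against the coarseness of the dispersal biology, and
  no projection is prescribed for the inputs.
* The source description equates 540 km/week with 90 km/night, which is
  arithmetically 630/7; the package implements the 540 km radius and does
  not attempt to reconcile the per-night figure.

## The weekly step and the engine

Order within a step: **growth → short-range dispersal → long-range jumps →
Allee check**. Only the Allee check's position (end of step) is fixed by
the biology ("required by the end of the time step"); the rest of the
order is a declared convention, stated here once and used everywhere.
Weekly rates come from the calendar month containing the week's start.

Replicates differ only through the jump RNG. Replicate `k` runs under a
seed derived from the master seed by a fixed affine map, so any replicate
is reproducible in isolation; the engine restores the global RNG state
after running. Identical master seeds give bitwise-identical outputs
(tested).

Every step's mass bookkeeping (growth delta, boundary/sea loss, jump loss,
Allee extinction) is recorded; the accounting identity closes to rounding
(residuals at the 1e-6-relative level are float accumulation, itemised in
the run log rather than hidden).

## Synthetic climate worlds

`generate_climate()` builds forcing as
`base − lapse·(row−1) + A_s sin(2π(doy−φ)/365) + A_d sin(2π·hour/24) + noise`,
with the wilting fraction built analogously and clipped to [0, 1], on a
365-day calendar (no leap handling). Row 1 is the northern, warmest row —
a southern-hemisphere-like layout. Three packaged presets fix the study
conditions:

* `benign_uniform` — 27 °C, wet, no variability: every cell grows at
  exactly `r_ref`. The control against which engine arithmetic is checked.
* `tropics_to_temperate` — 30 °C at the tropical edge falling to 8 °C at
  the temperate edge, 7 °C seasonal amplitude phased for a warm January,
  4 °C diurnal cycle. Spans permanently suitable through winter-lethal
  cells with a single monotone boundary.
* `arid_pulse` — uniform cool 16 °C (where `r_p` ≈ 0.009/day) with a dry
  season (wilting base 0.3, amplitude 0.5, peak mid-July) crossing the
  0.5 threshold. Desiccation mortality is capped at 0.2 × 0.5 = 0.1/day,
  which can never overcome growth at 27 °C; a cool baseline is the
  realistic regime in which drying actually flips the sign of the net
  rate. Because the forcing is sinusoidal, the month in which the mean
  wilting is within a few hundredths of 0.5 is a knife-edge; the tests
  therefore assert the sign flip for months clearly inside (≥ 0.55) and
  clearly outside (≤ 0.45) the dry season rather than at the crossing
  itself.

The generator emulates the *statistical structure* the model consumes —
gradients, seasonality, diurnal cycles, aridity pulses — not real weather:
there is no temporal autocorrelation, no interannual variability, no
spatially correlated noise, and no projection. Passing tests on these
worlds validate the model's mechanisms and their coupling, not predictive
skill on real landscapes.

## Climate I/O

NetCDF is the native format (SMAP-like variable names `surface_temp` in
Kelvin and `land_fraction_wilting`; CF-style time axis); Kelvin→Celsius
conversion happens exactly once, at the file boundary. The reader accepts
any regular planar grid and does not implement the EASE-grid projection of
the real satellite product — the model's mechanisms do not depend on it,
and real-data users can re-grid upstream. Land is inferred from climate
validity: any cell with a missing temperature timestep is sea, carries no
population, and propagates `NA` rates. Wilting values outside [0, 1] are
rejected with a count, and irregular time gaps are reported, never
silently interpolated. Raster output is NetCDF (full fidelity), 32-bit
float TIFF with a JSON geometry sidecar (no GeoTIFF tags), or long CSV.

## Problem sizes and runtime

The shipped tests run on worlds up to 30 × 6 cells over one year of
3-hourly forcing (~2 900 timesteps), with up to five replicates of
53 weekly steps — sizes chosen so the full suite exercises every mechanism
(including the Monte-Carlo uniformity check of jump destinations at ~5 000
draws) in a few minutes on one CPU. All scaling-sensitive code paths
(kernel convolution, jump-destination precomputation, month binning) are
vectorised and behave linearly in cells × timesteps; 60 × 60 × 1-year
worlds generate in seconds.

## Known limitations

* Life stages are collapsed into one rate; no stage structure or
  development delays.
* No wind-driven, anisotropic long-range transport; jump destinations are
  isotropic within the radius.
* `K` and θ are spatially uniform; host availability and crop phenology
  are not modelled.
* High-moisture/rainfall mortality is deliberately excluded.
* Establishment classification is a sign test on the annual mean rate; it
  ignores variance, so a cell alternating +2 and −1.99 classifies the same
  as one at a constant +0.005/day.
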