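---
title: "Methods: a climate-driven fire-succession model and caribou winter-habitat analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a climate-driven fire-succession model and caribou winter-habitat analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borealfire)
```

## The model

`borealfire` is a desk-scale, spatially explicit stochastic landscape model
for boreal and arctic fire-vegetation dynamics, together with the habitat
analytics needed to ask what a changing fire regime does to lichen-producing
winter range for migratory tundra caribou. It runs on a rectangular lattice
(nominally 1-km pixels) at an annual time step over five land-cover classes:
rock/ice, tundra, black spruce, white spruce and deciduous. The per-pixel
state is the vegetation class plus the stand age — years since last fire —
with a sentinel age of −1 on rock/ice, where "time since fire" has no
meaning.

Each simulated year proceeds in four stages:

1. **Flammability.** Every pixel gets an annual flammability
   $$f = \mathrm{clamp}_{[0,1]}\!\big(\,\sigma(\beta_0 + \beta_T T + \beta_P P)\cdot
   s_{veg} \cdot \min(1, a / A_{fuel})\,\big),$$
   where $\sigma$ is the logistic function, $T$ and $P$ are the
   growing-season temperature (°C) and precipitation (mm) of that pixel-year,
   $s_{veg}$ is a class multiplier (rock/ice pinned to 0; tundra well below
   spruce, reflecting that tundra fires are fewer and smaller), and the last
   factor is a fuel-buildup ramp in stand age $a$: a stand that burned last
   year carries no fuel and cannot reburn, and fuel saturates at
   $A_{fuel}$ years. Setting `fuel_age_scale <= 0` disables the ramp, which
   gives a constant-hazard regime used by the stationarity check below.
2. **Ignition.** Each pixel ignites independently when a uniform draw falls
   below its flammability (`ignite()`), optionally capped at
   `max_ignitions` by random subsampling (uncapped by default).
3. **Spread.** Each ignition grows by a breadth-first front on the
   8-neighborhood (`spread_fire()`): every newly burning cell attempts each
   not-yet-burned neighbor exactly once, succeeding with probability
   $\mathrm{clamp}_{[0,1]}(\text{spread\_factor} \times f_{neighbor})$.
   Fires ignited the same year spread sequentially in RNG-shuffled order and
   exclude cells already burned that year, so per-year burn masks are
   well-defined disjoint unions of connected fires. A consequence of strict
   lattice adjacency is that fuel separated by a ≥ 2-cell band of rock/ice
   is unreachable; fires never cross it.
4. **Succession and aging** (`apply_transitions()`). Burned black or white
   spruce resets to early-successional deciduous at age 0 and is scheduled
   to return to a climax spruce class — its own class with probability
   `spruce_target_prob` (default 0.9), otherwise the other spruce — after a
   delay drawn uniformly on `decid_to_spruce_range` (default 25–75 y) and
   multiplied by the fire-severity factor $1 + k\,\log_{10}(\text{fire
   area} + 1)$; fire area is the severity proxy (topographic severity is a
   non-goal). Burned deciduous self-replaces at age 0, keeping its climax
   target but resampling the delay, so repeated burning postpones climax
   spruce indefinitely. Burned tundra self-replaces; there is no treeline
   movement in either direction. Unburned fuel ages by one year, and an
   unburned deciduous stand whose age reaches its scheduled due age becomes
   its climax spruce class *with age preserved*: habitat classification runs
   on time since fire, not time in class, so maturation must not rejuvenate
   a stand. (Whether maturation should instead reset age is genuinely open;
   preserving it is the choice consistent with an age-threshold habitat
   rule, and it is what the transition bookkeeping tests pin down.)

Ensembles (`run_ensemble()`) run replicates from independently spun-up
landscapes (`spin_up()` iterates the model under a stationary baseline
climate sampler until ages and composition equilibrate with the fire
regime). One master seed derives an independent child seed per replicate, so
every ensemble is bit-reproducible.

## Synthetic study conditions

No real land-cover, climate or burn-perimeter data are required; the
`generate_*()` family builds structurally faithful stand-ins:

* **Landscapes** (`generate_landscape()`): a seeded multinomial draw over
  the five classes, smoothed into patches by three majority-filter passes
  (fire spread is degenerate on salt-and-pepper maps), then a quota-repair
  pass that returns class counts to their targets, keeping empirical
  frequencies within 2% of the requested proportions. Initial stand ages
  are geometric with mean `mean_age` (default 80 y) — the stationary
  time-since-fire distribution under a constant hazard — and initial
  deciduous stands get a succession schedule (climax class drawn with equal
  odds) so they can mature even if never burned.
* **Climate** (`generate_climate()`): temperature is baseline + linear
  decadal trend + per-row latitudinal gradient + white noise;
  precipitation analogously (floored at 0 mm). White noise is the simplest
  structure that exercises interannual flammability variability;
  autocorrelated weather, seasonality and drought persistence are real-data
  features the generator does not emulate. `generate_climate_pair()` builds
  a "warm" and a "hot" trajectory on identical noise, differing only in
  trend (defaults 0.3 vs 0.6 °C/decade), so scenario contrasts isolate the
  warming signal.
* **Herd ranges** (`generate_range_masks()`): connected blobs grown around
  anchors by jittered-distance accretion to a target fraction of the domain
  (within 1%). Masks are built in list order; overlapping requests simply
  overlap.
* **Historical fire records** (`generate_historical_record()`): per-year
  ignitions at rate `burn_rate / mean_fire_size` grown into connected
  patches with geometric sizes, so the expected annual burned fraction is
  `burn_rate`; labelled per fire like a burn-perimeter database.

## Default parameters and their calibration

The regression that drives flammability in the original operational model is
not public; the logistic parameterization above preserves its stated
dependencies (climate, vegetation, time since fire) with every coefficient
exposed, and should not be mistaken for calibrated operational values. The
package defaults were fixed once, by two considerations:

* **Baseline regime.** Published decadal fire characteristics for the
  emulated region imply a domain-wide burned fraction of roughly 0.3% per
  year. With `beta_t = 0.15`, `beta_p = -0.006` and baseline climate (12 °C,
  150 mm), `beta0 = -7.4` and `spread_factor = 150` give ≈ 0.3–0.4%/yr with
  mean fire sizes of ≈ 4–5 km² on the 50×50 reference landscape — small
  desk-scale analogues of the reported regime.
* **Climate sensitivity.** `beta_t = 0.15` per °C makes the hot trajectory's
  end-of-century flammability about 2.2× baseline (warm ≈ 1.5×), matching
  the "roughly a doubling of area burned" scale of published projections. A
  steeper sensitivity saturates the desk-scale domain (every pixel burns
  within the horizon) and destroys the contrast the analyses are about.

Vegetation multipliers default to black spruce 1.0, white spruce 0.8,
deciduous 0.4, tundra 0.25, rock/ice 0 (fixed): tundra burns at a quarter of
the rate of black spruce, and all tundra types are treated identically. The
fuel ramp `A_fuel` defaults to 30 y.

## Habitat analytics

Winter habitat is a binary proxy: a pixel qualifies iff its class is tundra
or spruce **and** its stand age is *strictly* greater than the threshold
(default 60 y, the forage-lichen recovery horizon). A stand aged exactly 60
does not qualify; the threshold and class set are configurable
(`habitat_config()`).

* `habitat_timeseries()` reports per run-year-range habitat areas split into
  tundra and spruce components, with across-run 5th/95th percentile
  envelopes and medians per year. All quantiles in the package use the
  nearest-rank convention (no interpolation), so envelope values are always
  observed areas.
* `representative_run()` selects the replicate whose annual area-burned
  series has the highest Pearson correlation with the per-year across-run
  median series; ties break to the lowest index, zero-variance replicates
  are skipped, and an all-constant ensemble is an explicit error.
* `relative_flammability()` is the per-pixel fraction of all run-years in
  which the pixel burned; `top_flammability_mask()` thresholds it at the
  k-th largest value over fuel pixels, $k = \lfloor \text{fraction}\cdot n
  \rfloor$, with threshold ties all included (an all-equal map flags the
  whole fuel domain). `range_overlap_percent()` then gives the percent of a
  herd range inside the flagged area.
* `flammability_difference()` is the per-pixel `hot − warm` difference
  (positive = the hotter trajectory burns that pixel more often); the
  convention is recorded in the result.
* `percent_change()` is the plain relative change of two areas;
  `format_percent_change()` rounds to whole percent at magnitude ≥ 1 and to
  one decimal below, the convention used when reporting habitat changes.
* Fire-regime statistics (`regime_stats()`) attribute a fire to a range or
  vegetation filter if at least one burned pixel intersects it, and count
  only the intersected area — whole-fire attribution mirrors perimeter
  databases, intersected areas keep class-wise sums additive. Decadal
  summaries use the sample SD (n − 1). Simulation years 1..90 map to the
  2011–2100 calendar; decade *d* is years 10(d−1)+1..10d, labelled
  "2010s".."2090s". For ensemble replicates the burned class is the
  pre-fire vegetation of that year.
* `calibration_distance()` compares simulated to historical regimes by a
  normalized squared distance over three period aggregates (mean annual
  count, mean fire size, mean annual area), falling back to absolute
  differences when a historical term is zero; `calibrate_intercept()` is a
  deliberate grid-search diagnostic, not a gradient tuner.

## The paired-scenario experiment

`paired_scenario_experiment()` is the package's headline configuration: a
two-zone landscape (`two_zone_landscape()`, tundra-dominated north over
spruce-dominated south, emulating an arctic-wintering and a
boreal-wintering herd range), one range blob per zone, and warm/hot climate
members sharing seeds and noise. Habitat change is the percent change from
the first to the last decade of the across-run median annual habitat series.
`directional_contrast()` repeats the experiment over independent seeds and
reports, as fractions of pairs, whether the hot member burns more, loses
more habitat, and whether the spruce range loses a larger fraction than the
tundra range.

## Problem sizes, numerics, and what the tests do and do not show

The shipped checks use deliberate desk-scale sizes: toy oracle comparisons
on ≤ 10×10 grids with 3–5 replicates; full structural invariants on a
50×50, 10-replicate, 90-year ensemble; a 1,200-year constant-hazard spin-up
on 40×40 (mean stand age within 15% of the closed form $(1-p)/p$);
intercept recovery by grid search on 30×30 over 80-year records (recovery
to within the 0.4 grid spacing); and 20 independent 30×30 warm/hot pairs
with two replicates each for the directional contrast. The acceptance
script's simulated quantities come from a 40×40, 10-replicate, 90-year
pair. These sizes are the package's chosen study conditions; scaling any of
them up is a matter of configuration, not code.

Numerical conventions worth knowing: flammability is clamped to [0, 1]
after all multiplications; spread probabilities likewise; transition times
round to the nearest integer year with a floor of 1; degenerate inputs
(all-constant area-burned series, empty range masks, zero habitat, zero
start area in a percent change, zero historical denominators) raise explicit
errors or documented fallbacks rather than propagating NaN.

Passing tests show the mechanics are right — transitions, bookkeeping,
statistics and their oracles — and that the *direction* of the scenario
contrast is robust under the synthetic conditions. They do not show that
magnitudes transfer to the real 570,000-km² domain: the synthetic landscape
has no topography, no real geography, white-noise climate, a single
parameterized flammability response, and percent changes at desk scale are
much larger than full-scale ones because individual fires are large relative
to the domain. Known limitations shared with the emulated model: one
homogeneous tundra class, no shrubification or treeline advance, no
suppression, no sub-annual fire weather, and fire area as the only severity
input.
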