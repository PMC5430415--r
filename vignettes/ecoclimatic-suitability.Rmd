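---
title: "Ecoclimatic suitability modelling with ecoclimex: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecoclimatic suitability modelling with ecoclimex: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclimex)
```

# The model

`ecoclimex` implements a CLIMEX-style mechanistic niche model: climate
is translated into a species' potential for population growth and its
probability of surviving the unfavourable season, and the two are
combined into a single Ecoclimatic Index (EI) on a 0–100 scale.  The
default parameterization describes the polyphagous shot-hole borer
*Euwallacea fornicatus*, a wet-tropical ambrosia beetle.

## The weekly year

All internal computation runs on a year of exactly 52 weeks × 7 days
(364 days).  Monthly climatologies are resolved to weeks in two ways:

* **rates** (temperatures, humidity) by linear interpolation between
  month mid-points, wrapping December→January, so constant monthly
  input stays constant;
* **totals** (precipitation) by dividing each month's total across the
  weeks whose mid-point falls in that month, which conserves the annual
  sum exactly (months carry 4 or 5 weeks, so weekly rain is piecewise
  constant rather than smooth).

The fixed 52 × 7 calendar keeps weekly degree-day sums and stress
accumulations exact and reproducible; no leap-year bookkeeping exists.

## Growth

The weekly Growth Index is `GI_w = TI_w × MI_w`.

**Temperature Index.**  A trapezoid over the weekly mean temperature
`tavg = (tmax + tmin)/2`: zero at or below the lower development
threshold `DV0` (15 °C — immature stages do not survive below it),
rising to 1 at the lower optimum `DV1` (26 °C), flat to the upper
optimum `DV2` (35 °C), falling to zero at the upper limit `DV3`
(40 °C).

**Moisture Index.**  The same trapezoid shape over soil moisture as a
fraction of bucket capacity, with knots `SM0–SM3` = 0.05, 0.3, 1, 2.5.
Values above 1 express waterlogging, which is why the axis extends to
`SM3` = 2.5.

**Soil-moisture bucket.**  Each cell carries a single bucket (capacity
100 mm by default).  Weekly evaporative demand is the documented
closed form `E = max(0, k·tavg) · (1 − rh/100) · 7` mm/week with
`k = 0.8` mm·day⁻¹·°C⁻¹ and `rh` the mean of the 09:00 and 15:00
humidities.  The bucket gains the weekly rainfall and loses the
*actual* evapotranspiration `E · min(1, sm)` — the demand scaled by
bucket fullness, a standard linear-reservoir closure.  This scaling is
a deliberate design choice: if the full demand were withdrawn
regardless of content, every constant climate would either drain to
zero or fill to the cap, the Moisture Index would be degenerate at
steady state, and an "ideal" warm–wet climate could never score a high
EI.  With the linear closure a constant climate equilibrates at
`sm* = rain/demand`, which behaves correctly across the whole
wet-to-arid gradient.  The annual cycle is iterated to a periodic
steady state (max weekly change < 10⁻⁶, at most 50 cycles), making the
result independent of the initial bucket content; the weekly update is
a contraction whenever demand is positive, so convergence is geometric.

The Annual Growth Index is `GI_A = 100 · mean(GI_w)`.

## Stress and survival

Four stresses accumulate linearly: each week beyond the threshold
contributes `|rate| × excess`, summed over the year, scaled by 100 and
capped at 100 (lethal).  Cold stress reads the weekly *minimum*
temperature against `TTCS` (−10 °C at 0.005 week⁻¹) and heat stress
the weekly *maximum* against `TTHS` (42 °C at 0.0002 week⁻¹) — the
source climatology is silent on which temperature the survival limits
bind to, and extremes are the physiologically defensible choice.  Dry
and wet stress read the weekly soil moisture against `SMDS` (0.05 at
0.001 week⁻¹) and `SMWS` (2.5 at 0.005 week⁻¹).  Accumulation is
additive, not compounding: the parameterization supplies only a
threshold and a weekly rate, and the linear reading is the simplest
faithful one.

Survival is the Annual Stress Index
`SI = (1 − CS/100)(1 − DS/100)(1 − HS/100)(1 − WS/100)`; any single
lethal stress annihilates it.  The stress-interaction term that the
full CLIMEX framework allows is fixed to 1, and no Diapause Index is
modelled — the species is wet-tropical and its parameter set contains
no diapause terms.

## The Ecoclimatic Index and its hard zeros

`EI = GI_A × SI`, then forced to zero — with every satisfied condition
recorded, not just the first — when any of the four limiting
conditions holds:

1. `GEN_LT_1`: annual degree-days above `DV0` fall short of `PDD` =
   373 DD per generation (the sum of ~237 DD egg-to-adult and ~136 DD
   of preoviposition);
2. `CS_GE_100`: cold stress reaches 100;
3. `TI_ZERO`: the Temperature Index is zero in every week;
4. `MI_ZERO`: the Moisture Index is zero in every week.

A lethal dry, heat or wet stress also zeroes EI through `SI`, but via
the product rather than a dedicated flag; such cells are identifiable
from the per-cell stress columns and are tracked separately from the
four named conditions.

## Classification

EI = 0 is unfavourable, (0, 10] marginal, (10, 20] favourable, and
above 20 highly favourable.  The boundary value 20 itself is
*favourable*: the class definitions partition the axis with closed
upper ends, and that convention is applied literally even where a map
legend might round it the other way.

# Parameters

| Mnemonic | Meaning | Units | Fitted | Template |
|---|---|---|---|---|
| DV0 | lower development threshold | °C | 15 | 15 |
| DV1 | lower optimum | °C | 26 | 28 |
| DV2 | upper optimum | °C | 35 | 33 |
| DV3 | upper limit | °C | 40 | 36 |
| SM0–SM3 | moisture response knots | fraction | 0.05/0.3/1/2.5 | 0.35/0.7/1.5/2.5 |
| TTCS, THCS | cold stress threshold, rate | °C, week⁻¹ | −10, −0.005 | 2, 0 |
| TTHS, THHS | heat stress threshold, rate | °C, week⁻¹ | 42, 0.0002 | 37, 0.0002 |
| SMDS, HDS | dry stress threshold, rate | fraction, week⁻¹ | 0.05, −0.001 | 0.25, −0.01 |
| SMWS, HWS | wet stress threshold, rate | fraction, week⁻¹ | 2.5, 0.005 | 2.5, 0.002 |
| PDD | degree-days per generation | DD | 373 | disabled |

Stress rates are stored signed (cold and dry non-positive, heat and wet
non-negative) and consumed as magnitudes at the accumulation site; the
wet-tropical template's dry-stress rate is therefore sign-normalized to
−0.01 on construction.  The template's PDD of zero means "no generation
constraint" and is represented by an explicit disabled flag rather than
a zero divisor; in the flat parameter file the key `PDD = 0` round-trips
to that flag.  `validateParams()` returns named violations instead of
failing, so interactive exploration of candidate sets is cheap.

Two engine constants are deliberately configurable defaults rather than
species parameters: the bucket capacity (100 mm) and the demand
coefficient `k = 0.8`.  No test or reported quantity depends on their
exact values, only on the response-curve behaviour they induce.

# The synthetic climate generator

`generateSyntheticRegion()` emulates, on a configurable grid, the
large-scale structure of an East-Asian monsoon domain:

* annual mean temperature falls 0.7 °C per degree latitude northward
  from 25 °C at the southern edge, with a July-peaked seasonal
  amplitude growing from 4 °C in the south to ~18 °C in the north;
* a high plateau block (4500 m, smooth-edged) occupies the north-west
  quadrant and is cooled by the 6.5 °C/km lapse rate;
* annual precipitation decays from ~2000 mm at the south-east corner to
  under 100 mm at the north-west along the monsoon axis, with a
  summer-heavy monthly share; humidity tracks local wetness;
* a handful of seeded low-frequency cosine modes add smooth spatial
  noise, so grids are bit-reproducible given `(spec, seed)`.

The `"future"` scenario applies a spatially uniform +1.0 °C to maximum
and +1.2 °C to minimum temperature and +5% precipitation from January
to September, leaving humidity unchanged (whether humidity will change
is genuinely unclear, so the conservative choice is none).  These
deltas are the generator's defaults because they are the study
conditions being emulated, not tuning knobs.

What the generator does *not* emulate: real station density and
coverage error, coastlines and ocean moderation, interannual
variability (inputs are normals), terrain-following precipitation
shadows, or observational error.  Passing tests on synthetic grids
therefore demonstrate correctness of the computation and the right
qualitative response to the emulated gradients — not predictive skill
on real landscapes.

# Spatial plumbing

Grids are regular lon/lat with cells indexed row-major from the
south-west corner; cell area is `(111.32·cellsize)² · cos(lat)` km².
Station-to-grid interpolation is inverse-distance weighting over the
`k` nearest stations (haversine distances on a spherical Earth), with
temperatures reduced to sea level by the lapse rate before averaging
and re-elevated to the cell elevation after; a cell within a metre of
a station takes the station's values exactly.  Thin-plate-spline
interpolation over elevation is out of scope — IDW with a lapse-rate
adjustment is the documented stand-in, and the same IDW family is what
the downstream mapping workflow uses anyway.

Future climates come from additive anomaly ("delta") calibration:
`future = observed + (GCM future − GCM baseline)` per cell, variable
and month, which cancels the GCM's bias in absolute values.
Precipitation is additive with a floor at zero (the deltas "are
added"; a multiplicative variant would change the contract), humidity
is clamped to [0, 100], and any tmax/tmin inversion the deltas
introduce is repaired by swapping with a reported count.

Points are assigned to the cell whose centre is nearest, with ties on
cell edges broken toward the south-west cell.  Occurrence validation
counts a record as suitable when its containing cell is anything but
unfavourable; records outside the grid or in masked cells are excluded
from the denominator with a warning.

Grid and product I/O is long-format CSV with a `#`-prefixed metadata
header (tool version, configuration hash, seed); values are printed at
full precision so CSV round trips are bit-exact and identical
configuration plus seed yields bit-identical files.

# Downstream analyses

**Area summaries** weight by cell area, never cell counts; the
"potential distribution" denominator is the union of the three
favourable classes.  **Impact indices** score each limiting condition
per region as `round(10 × affected area / region area)` with half-up
rounding — the published definition fixes only the 0–10 range and the
area proportionality, so the rounding rule is documented here.
**Range shifts** are displacements of the area-weighted latitude
centroid of a class; the metric is undefined (returned as `NA`, with a
warning) when the class is absent from either scenario, and is exact
under translation up to the slow variation of `cos(lat)` weights.
**Sensitivity analysis** perturbs one parameter at a time — default
±5% and ±10% of the fitted value, the published experiment's exact
magnitudes being unavailable — and records the mean EI over all
unmasked cells, zeros included, against the baseline.

# Numerical choices

* Spin-up tolerance 10⁻⁶ on the max weekly change, 50-cycle budget;
  initial bucket content 0.
* Test comparisons use relative tolerance 10⁻⁹ unless a looser one is
  stated with its reason (e.g. centroid translation under cos-lat
  weights at 10⁻³).
* The waterlogging cap is `SM3 + 1`, keeping the bucket bounded while
  leaving the wet-stress range above `SMWS` reachable.
* Degenerate inputs fail loudly and early: non-finite climatologies,
  non-positive capacity, empty regions and out-of-range EI are
  rejected, never silently repaired (the one documented repair —
  tmax/tmin swaps after delta calibration — reports its count).
* Problem sizes: the test suite and the acceptance script run the full
  pipeline on a 50 × 50 × 0.5° grid (2500 cells) and smaller; a full
  scenario pair completes in a few seconds, chosen to keep the whole
  suite comfortably interactive.

# Known limitations and open directions

* The sensitivity direction for `DV1` measures as *negative* here
  (narrowing the optimum plateau from below reduces growth), which is
  what a trapezoidal Temperature Index implies; a published account of
  the same experiment reports the opposite sign for this one
  parameter.  The direction is reported, never asserted, and the
  robust directions (`DV0`, `SM0`–`SM3`) are asserted instead.
* Stress accumulation is linear and non-compounding; a compounding
  variant would darken cold boundaries but has no basis in the
  threshold-plus-rate parameterization.
* The bucket is single-layer with no runoff term beyond the cap and no
  snow phase; high-latitude winter moisture is therefore crude.
* No diapause, no irrigation scenarios, no stress interaction, and no
  multi-year "compare years" mode.
* Real-data products (station files, GCM anomaly grids) are consumed
  through the documented CSV schemas; retrieval clients are out of
  scope.
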