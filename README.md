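# ecoclimex

Mechanistic ecoclimatic suitability modelling for pest risk mapping,
parameterized for the polyphagous shot-hole borer *Euwallacea
fornicatus* — an ambrosia beetle of Southeast Asian origin that attacks
over 200 broadleaf host species and is an emerging quarantine concern
in subtropical forestry and horticulture.

The package answers the question a pest-risk analyst asks of a climate
normal: *could this species persist here, and how comfortably?*  It
does so with a CLIMEX-style process model rather than a correlative
one: population growth and survival are built from the species'
measured physiology, so the model extrapolates to unsampled climates
and future scenarios.

## The model

For each location the 12-month climatology is resolved onto a 52-week
year.  Weekly population growth is the product of two trapezoidal
responses,

- a Temperature Index `TI(t)` rising from 0 at the lower development
  threshold `DV0` to 1 across the optimum `[DV1, DV2]` and back to 0 at
  the upper limit `DV3`, and
- a Moisture Index `MI(s)` over soil moisture `s` (a fraction of a
  100 mm bucket fed by rainfall and drained by evaporative demand),
  shaped by `SM0 <= s <= SM3` with optimum `[SM1, SM2]`;

their annual mean scaled to 0–100 is the Annual Growth Index `GI_A`.
Survival through the unfavourable season is the Annual Stress Index

    SI = (1 - CS/100)(1 - DS/100)(1 - HS/100)(1 - WS/100),

where cold, dry, heat and wet stress accumulate weekly beyond their
thresholds (`TTCS`, `SMDS`, `TTHS`, `SMWS`) at fixed weekly rates, each
capped at the lethal value 100.  The Ecoclimatic Index is

    EI = GI_A x SI,

on a 0–100 scale, forced to 0 whenever any of four limiting conditions
holds: fewer than one generation per year (annual degree-days above
`DV0` below `PDD` = 373), cold stress at 100, all-year `TI = 0`, or
all-year `MI = 0`.  EI is classified as unfavourable (EI = 0),
marginal (0 < EI ≤ 10), favourable (10 < EI ≤ 20) or highly favourable
(EI > 20).

Around the engine the package provides station-to-grid inverse-distance
interpolation with a lapse-rate elevation adjustment, additive GCM
anomaly ("delta") calibration of future climates, a seeded synthetic
monsoon-gradient climate generator, favourability classification and
area summaries, limiting-factor attribution with per-region impact
indices, current-versus-future comparison (EI change, class
transitions, latitudinal range shifts), occurrence-record validation,
and one-at-a-time parameter sensitivity analysis.

## Worked example

A warm, humid, seasonless climate is ideal — the "incubator" case:

```r
library(ecoclimex)
p <- defaultFornicatusParams()
mc <- MonthlyClimate(tmax = rep(33, 12), tmin = rep(24, 12),
                     prcp = rep(160, 12), rh09 = rep(85, 12),
                     rh15 = rep(65, 12))
runLocation(mc, p)
#> CellResult: EI = 100.00 (GI_A 100.00, SI 1.0000)
#>   stresses CS 0.0 HS 0.0 DS 0.0 WS 0.0; DD 4914 -> 13.17 generations
```

Growth is unconstrained every week (`GI_A` = 100), no stress
accumulates (`SI` = 1), and the 4914 annual degree-days support ~13
generations, so `EI = 100` — attainable only under such constant
conditions.

A seeded synthetic monsoon-gradient region (warm wet south-east, arid
north-west, cold high plateau) behaves like a miniature study area:

```r
spec <- GridSpec(98, 18, 0.5, 50, 50)     # 25 x 25 degrees, 2500 cells
cur <- runGrid(generateSyntheticRegion(spec, seed = 1, "current"), p)
areaSummary(cur)
#>               class area_km2 pct_region pct_potential
#> 1      unfavourable  2433296       36.8            NA
#> 2          marginal   963695       14.6          23.0
#> 3        favourable   943833       14.3          22.5
#> 4 highly_favourable  2279779       34.4          54.4
```

About a third of the region is climatically closed to the species
(cold, too few degree-days, or too dry), and highly favourable habitat
dominates the suitable remainder.  Warming the same region by the
scenario deltas (+1.0 °C tmax, +1.2 °C tmin, +5% Jan–Sep
precipitation) expands the range and pushes it poleward:

```r
fut <- runGrid(generateSyntheticRegion(spec, seed = 1, "future"), p)
rangeShift(cur, fut, "highly_favourable")
#> [1] 1.128886        # degrees latitude, northward
eiDifference(cur, fut)$summary
#>   maxIncrease maxDecrease     mean
#> 1    28.11934           0 2.420924
```

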