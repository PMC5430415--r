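# Weekly growth/stress engine.  The model year is exactly 52 weeks of 7
# days (364 days): arithmetic on weekly sums stays exact and every
# monthly quantity maps onto 52 weekly values.

WEEKS <- 52L
DAYS_PER_WEEK <- 7

#' Interpolate a 12-month climatology to 52 weekly values
#'
#' Rate-like quantities (temperature, humidity) are interpolated
#' linearly between month mid-points (each month centred at its
#' mid-week, wrapping December to January), so a constant monthly input
#' yields a constant weekly series.  Total-like quantities
#' (precipitation) are instead divided evenly across the weeks belonging
#' to each month, which conserves the annual sum exactly.
#'
#' @param values numeric(12) monthly values.
#' @param kind `"rate"` (default) for intensive quantities, `"total"`
#'   for monthly totals.
#' @return numeric(52) weekly values.
#' @examples
#' interpolateWeekly(rep(20, 12))             # constant preserved
#' sum(interpolateWeekly(1:12 * 10, "total")) # == sum(1:12 * 10)
#' @export
interpolateWeekly <- function(values, kind = c("rate", "total")) {
  kind <- match.arg(kind)
  if (length(values) != 12L || !all(is.finite(values))) {
    stop("values must hold 12 finite monthly values")
  }
  m <- if (kind == "rate") rateInterpMatrix() else totalInterpMatrix()
  as.numeric(m %*% values)
}

# 52 x 12 linear interpolation weights between month mid-points,
# wrapping around the year boundary.
rateInterpMatrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    mw <- WEEKS / 12                       # weeks per month
    centers <- (seq_len(12) - 0.5) * mw    # month mid-points, week units
    out <- matrix(0, WEEKS, 12L)
    for (w in seq_len(WEEKS)) {
      x <- w - 0.5
      if (x < centers[1L]) {               # before mid-January: Dec -> Jan
        f <- (x - (centers[12L] - WEEKS)) / mw
        out[w, 12L] <- 1 - f; out[w, 1L] <- f
      } else if (x >= centers[12L]) {      # after mid-December: Dec -> Jan
        f <- (x - centers[12L]) / mw
        out[w, 12L] <- 1 - f; out[w, 1L] <- f
      } else {
        i <- findInterval(x, centers)
        f <- (x - centers[i]) / mw
        out[w, i] <- 1 - f; out[w, i + 1L] <- f
      }
    }
    cache <<- out
    out
  }
})

# 52 x 12 allocation of monthly totals: each week belongs to the month
# containing its mid-point and receives total / (weeks in that month).
totalInterpMatrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    month <- floor((seq_len(WEEKS) - 0.5) * 12 / WEEKS) + 1L
    n <- tabulate(month, 12L)
    out <- matrix(0, WEEKS, 12L)
    out[cbind(seq_len(WEEKS), month)] <- 1 / n[month]
    cache <<- out
    out
  }
})

#' Weekly temperature growth response
#'
#' The trapezoidal Temperature Index: 0 at or below `dv0`, rising
#' linearly to 1 at `dv1`, 1 across the optimum plateau
#' `[dv1, dv2]`, falling linearly to 0 at `dv3`, 0 beyond.
#'
#' @param tavg weekly mean temperature (degrees C), any length.
#' @param p a [SpeciesParams-class] object.
#' @return Temperature Index values in `[0, 1]`.
#' @export
temperatureIndex <- function(tavg, p) {
  trapezoid(tavg, p@dv0, p@dv1, p@dv2, p@dv3)
}

#' Weekly soil-moisture growth response
#'
#' The trapezoidal Moisture Index over soil moisture expressed as a
#' fraction of bucket capacity: 0 at or below `sm0`, 1 on `[sm1, sm2]`,
#' 0 at or above `sm3`, linear between.
#'
#' @param sm weekly soil moisture (fraction of capacity; > 1 means
#'   waterlogged), any length.
#' @param p a [SpeciesParams-class] object.
#' @return Moisture Index values in `[0, 1]`.
#' @export
moistureIndex <- function(sm, p) {
  trapezoid(sm, p@sm0, p@sm1, p@sm2, p@sm3)
}

trapezoid <- function(x, a, b, c, d) {
  up <- (x - a) / (b - a)
  down <- (d - x) / (d - c)
  pmin(pmax(pmin(up, down), 0), 1)
}

#' Weekly evaporative demand
#'
#' A simple temperature- and humidity-driven demand term for the
#' soil-moisture bucket: `E = max(0, k * tavg) * (1 - rh/100) * 7`
#' mm/week, with `rh` the mean of the 09:00 and 15:00 observations.
#' Demand is zero at or below 0 degrees C and in saturated air.
#'
#' @param tavg weekly mean temperature (degrees C).
#' @param rh09,rh15 relative humidity at 09:00 / 15:00 (percent).
#' @param k demand coefficient (mm per day per degree C; default 0.8).
#' @return evaporative demand (mm/week).
#' @export
weeklyEvaporation <- function(tavg, rh09, rh15, k = 0.8) {
  rh <- (rh09 + rh15) / 2
  pmax(k * tavg, 0) * (1 - rh / 100) * DAYS_PER_WEEK
}

#' One step of the soil-moisture bucket
#'
#' `sm_w = max(0, sm_prev + (rain - evap) / capacity)`, capped at
#' `smCap` (waterlogging is allowed above 1, up to `sm3 + 1` in the
#' engine).
#'
#' @param smPrev previous week's soil moisture (fraction, >= 0).
#' @param rain weekly rainfall (mm).
#' @param evap weekly evaporative demand (mm).
#' @param capacity bucket capacity (mm, > 0).
#' @param smCap upper cap on the moisture fraction.
#' @return updated soil moisture (fraction).
#' @export
updateSoilMoisture <- function(smPrev, rain, evap, capacity, smCap = 3.5) {
  if (any(capacity <= 0)) stop("capacity must be > 0")
  pmin(smCap, pmax(0, smPrev + (rain - evap) / capacity))
}

#' Spin the soil-moisture bucket up to its periodic steady state
#'
#' Each week the bucket gains the rainfall and loses the actual
#' evapotranspiration: the atmospheric demand scaled by bucket fullness,
#' `demand * min(1, sm)`, so a full bucket loses water at the demand
#' rate and a dry one loses nothing (a linear-reservoir bucket).  The
#' 52-week year is repeated until the weekly series changes by less than
#' `tol` between consecutive cycles (or `maxCycles` is reached), making
#' the steady state periodic and independent of the initial condition;
#' under constant forcing with `rain < demand` it converges to
#' `sm = rain / demand`, and to the waterlogging cap when rainfall
#' exceeds the demand.
#'
#' @param rain numeric(52) or a `52 x n` matrix of weekly rainfall (mm).
#' @param demand matching weekly evaporative demand (mm), from
#'   [weeklyEvaporation()].
#' @param capacity bucket capacity (mm).
#' @param smCap cap on the moisture fraction (engine uses `sm3 + 1`).
#' @param smInit initial moisture fraction.
#' @param tol convergence tolerance on the max weekly change.
#' @param maxCycles maximum annual cycles.
#' @return weekly soil moisture, same shape as `rain`.
#' @export
spinUpSoilMoisture <- function(rain, demand, capacity = 100, smCap = 3.5,
                               smInit = 0, tol = 1e-6, maxCycles = 50L) {
  if (capacity <= 0) stop("capacity must be > 0")
  vec <- is.null(dim(rain))
  rain <- as.matrix(rain); demand <- as.matrix(demand)
  stopifnot(nrow(rain) == WEEKS, all(dim(rain) == dim(demand)))
  n <- ncol(rain)
  sm <- matrix(0, WEEKS, n)
  carry <- rep(smInit, n)
  prev <- sm + Inf
  for (cycle in seq_len(maxCycles)) {
    for (w in seq_len(WEEKS)) {
      carry <- pmin(smCap, pmax(0, carry +
        (rain[w, ] - demand[w, ] * pmin(1, carry)) / capacity))
      sm[w, ] <- carry
    }
    if (max(abs(sm - prev)) < tol) break
    prev[] <- sm
  }
  if (vec) as.numeric(sm) else sm
}

#' Annual Growth Index from weekly temperature and moisture indices
#'
#' The weekly Growth Index is the product `ti * mi`; the annual index is
#' its mean over the 52 weeks scaled to 0-100.
#'
#' @param ti,mi numeric(52) weekly Temperature / Moisture Index values.
#' @return Annual Growth Index in `[0, 100]`.
#' @export
annualGrowthIndex <- function(ti, mi) {
  stopifnot(length(ti) == WEEKS, length(mi) == WEEKS)
  100 * sum(ti * mi) / WEEKS
}

#' Accumulate an annual stress index
#'
#' Each week beyond the threshold contributes `|rate| * excess`, where
#' the excess is `threshold - x` for `direction = "below"` (cold, dry)
#' and `x - threshold` for `direction = "above"` (heat, wet).  The
#' annual index is 100 times the summed weekly increments, capped at 100
#' (lethal).
#'
#' @param series numeric(52) weekly driver (tmin for cold, tmax for
#'   heat, soil moisture for dry/wet).
#' @param threshold stress threshold in the driver's units.
#' @param rate weekly stress rate; only its magnitude is used.
#' @param direction `"below"` or `"above"`.
#' @return annual stress in `[0, 100]`.
#' @export
accumulateStress <- function(series, threshold, rate, direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (!all(is.finite(series))) stop("series must be finite")
  excess <- if (direction == "below") threshold - series else series - threshold
  min(100, 100 * abs(rate) * sum(pmax(0, excess)))
}

#' Annual Stress Index
#'
#' The survival product
#' `SI = (1 - CS/100) (1 - DS/100) (1 - HS/100) (1 - WS/100)`:
#' any single lethal stress (100) annihilates it.
#'
#' @param cs,ds,hs,ws annual cold/dry/heat/wet stress, each in `[0, 100]`.
#' @return SI in `[0, 1]`.
#' @export
annualStressIndex <- function(cs, ds, hs, ws) {
  x <- c(cs, ds, hs, ws)
  if (any(x < 0 | x > 100)) stop("stress indices must lie in [0, 100]")
  (1 - cs / 100) * (1 - ds / 100) * (1 - hs / 100) * (1 - ws / 100)
}

#' Annual degree-days and generations
#'
#' Degree-days accumulate above the lower development threshold `dv0` at
#' 7 days per week: `dd = sum_w max(0, tavg_w - dv0) * 7`.  The number
#' of generations the year supports is `dd / pdd`; locations below one
#' generation cannot sustain a population.
#'
#' @param tavg numeric(52) weekly mean temperature (degrees C).
#' @param p a [SpeciesParams-class] object.
#' @return list with `ddAnnual` and `generations` (NA when the
#'   generation constraint is disabled).
#' @export
degreeDayGenerations <- function(tavg, p) {
  stopifnot(length(tavg) == WEEKS)
  dd <- sum(pmax(0, tavg - p@dv0)) * DAYS_PER_WEEK
  gen <- if (p@pddEnabled) dd / p@pdd else NA_real_
  list(ddAnnual = dd, generations = gen)
}

#' Run the engine for one location
#'
#' Composes the full weekly model for a single 12-month climatology:
#' monthly-to-weekly interpolation, the soil-moisture bucket spun up to
#' its periodic steady state, weekly Temperature and Moisture Indices,
#' the Annual Growth Index, the four annual stresses, degree-days and
#' generations, and the Ecoclimatic Index `EI = GI_A * SI` on the 0-100
#' scale.  EI is forced to 0 - with every satisfied condition recorded
#' in `limitingFlags` - when generations < 1 (`GEN_LT_1`), cold stress
#' reaches 100 (`CS_GE_100`), the Temperature Index is 0 in every week
#' (`TI_ZERO`), or the Moisture Index is 0 in every week (`MI_ZERO`).
#'
#' @param mc a [MonthlyClimate-class] object.
#' @param p a [SpeciesParams-class] object.
#' @param capacity soil bucket capacity (mm; default 100).
#' @param evapK evaporative demand coefficient (see [weeklyEvaporation()]).
#' @return a [CellResult-class] object (weekly diagnostics in the
#'   `weekly` slot: week, tavg, tmin, tmax, rain, sm, ti, mi, gi).
#' @examples
#' mc <- MonthlyClimate(tmax = rep(35, 12), tmin = rep(25, 12),
#'                      prcp = rep(150, 12), rh09 = rep(80, 12),
#'                      rh15 = rep(60, 12))
#' runLocation(mc, defaultFornicatusParams())
#' @export
runLocation <- function(mc, p, capacity = 100, evapK = 0.8) {
  stopifnot(is(mc, "MonthlyClimate"), is(p, "SpeciesParams"))
  v <- validateParams(p)
  if (length(v)) stop("invalid parameter set: ", paste(v, collapse = "; "))

  tmaxW <- interpolateWeekly(mc@tmax, "rate")
  tminW <- interpolateWeekly(mc@tmin, "rate")
  tavgW <- (tmaxW + tminW) / 2
  rainW <- interpolateWeekly(mc@prcp, "total")
  rh09W <- interpolateWeekly(mc@rh09, "rate")
  rh15W <- interpolateWeekly(mc@rh15, "rate")

  evapW <- weeklyEvaporation(tavgW, rh09W, rh15W, k = evapK)
  smW <- spinUpSoilMoisture(rainW, evapW, capacity = capacity,
                            smCap = p@sm3 + 1)

  ti <- temperatureIndex(tavgW, p)
  mi <- moistureIndex(smW, p)
  giA <- annualGrowthIndex(ti, mi)

  cs <- accumulateStress(tminW, p@ttcs, p@thcs, "below")
  hs <- accumulateStress(tmaxW, p@tths, p@thhs, "above")
  ds <- accumulateStress(smW, p@smds, p@hds, "below")
  ws <- accumulateStress(smW, p@smws, p@hws, "above")
  si <- annualStressIndex(cs, ds, hs, ws)

  dd <- degreeDayGenerations(tavgW, p)

  flags <- character()
  if (p@pddEnabled && dd$generations < 1) flags <- c(flags, "GEN_LT_1")
  if (cs >= 100) flags <- c(flags, "CS_GE_100")
  if (all(ti == 0)) flags <- c(flags, "TI_ZERO")
  if (all(mi == 0)) flags <- c(flags, "MI_ZERO")

  ei <- giA * si
  if (length(flags)) ei <- 0

  new("CellResult",
      giA = giA, cs = cs, hs = hs, ds = ds, ws = ws, si = si,
      ddAnnual = dd$ddAnnual, generations = dd$generations,
      ei = ei, limitingFlags = flags,
      weekly = data.frame(
        week = seq_len(WEEKS), tavg = tavgW, tmin = tminW, tmax = tmaxW,
        rain = rainW, sm = smW, ti = ti, mi = mi, gi = ti * mi
      ))
}

#' Construct a monthly climatology
#'
#' @param tmax,tmin numeric(12) monthly mean daily max/min temperature (degrees C).
#' @param prcp numeric(12) monthly precipitation totals (mm).
#' @param rh09,rh15 numeric(12) relative humidity at 09:00 / 15:00 (percent).
#' @return a validated [MonthlyClimate-class] object.
#' @export
MonthlyClimate <- function(tmax, tmin, prcp, rh09, rh15) {
  new("MonthlyClimate", tmax = as.numeric(tmax), tmin = as.numeric(tmin),
      prcp = as.numeric(prcp), rh09 = as.numeric(rh09),
      rh15 = as.numeric(rh15))
}

# Vectorized engine over the cells of a ClimateGrid: same arithmetic as
# runLocation, on 52 x n matrices.  Returns a per-cell data.frame.
runCellsMatrix <- function(grid, p, capacity = 100, evapK = 0.8) {
  keep <- which(grid@mask)
  n <- length(keep)
  R <- rateInterpMatrix(); Tt <- totalInterpMatrix()
  tmaxW <- R %*% t(grid@tmax[keep, , drop = FALSE])
  tminW <- R %*% t(grid@tmin[keep, , drop = FALSE])
  tavgW <- (tmaxW + tminW) / 2
  rainW <- Tt %*% t(grid@prcp[keep, , drop = FALSE])
  rhW <- (R %*% t(grid@rh09[keep, , drop = FALSE]) +
          R %*% t(grid@rh15[keep, , drop = FALSE])) / 2
  evapW <- pmax(evapK * tavgW, 0) * (1 - rhW / 100) * DAYS_PER_WEEK
  smW <- spinUpSoilMoisture(rainW, evapW, capacity = capacity,
                            smCap = p@sm3 + 1)

  ti <- trapezoid(tavgW, p@dv0, p@dv1, p@dv2, p@dv3)
  mi <- trapezoid(smW, p@sm0, p@sm1, p@sm2, p@sm3)
  giA <- 100 * colSums(ti * mi) / WEEKS

  cs <- pmin(100, 100 * abs(p@thcs) * colSums(pmax(p@ttcs - tminW, 0)))
  hs <- pmin(100, 100 * abs(p@thhs) * colSums(pmax(tmaxW - p@tths, 0)))
  ds <- pmin(100, 100 * abs(p@hds) * colSums(pmax(p@smds - smW, 0)))
  ws <- pmin(100, 100 * abs(p@hws) * colSums(pmax(smW - p@smws, 0)))
  si <- (1 - cs / 100) * (1 - ds / 100) * (1 - hs / 100) * (1 - ws / 100)

  dd <- colSums(pmax(tavgW - p@dv0, 0)) * DAYS_PER_WEEK
  gen <- if (p@pddEnabled) dd / p@pdd else rep(NA_real_, n)

  genLt1 <- if (p@pddEnabled) gen < 1 else rep(FALSE, n)
  csGe100 <- cs >= 100
  tiZero <- colSums(ti) == 0
  miZero <- colSums(mi) == 0

  ei <- giA * si
  ei[genLt1 | csGe100 | tiZero | miZero] <- 0

  data.frame(
    cell = keep, giA = giA, cs = cs, hs = hs, ds = ds, ws = ws, si = si,
    ddAnnual = dd, generations = gen, ei = ei,
    GEN_LT_1 = genLt1, CS_GE_100 = csGe100, TI_ZERO = tiZero,
    MI_ZERO = miZero
  )
}
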