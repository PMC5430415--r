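# Shared fixtures, all built in code.

# constant monthly climatology (an "incubator" climate)
constantClimate <- function(tmax = 35, tmin = 25, prcp = 150,
                            rh09 = 80, rh15 = 60) {
  MonthlyClimate(tmax = rep(tmax, 12), tmin = rep(tmin, 12),
                 prcp = rep(prcp, 12), rh09 = rep(rh09, 12),
                 rh15 = rep(rh15, 12))
}

# small monsoon-gradient grid used across suites
testSpec <- function(n = 20L, cellSize = 1) {
  GridSpec(98, 18, cellSize, n, n)
}

# a uniform ClimateGrid replicating one climatology over every cell
uniformGrid <- function(spec, mc) {
  n <- nCells(spec)
  rep12 <- function(x) matrix(rep(x, each = n), n, 12L)
  ClimateGrid(spec, tmax = rep12(mc@tmax), tmin = rep12(mc@tmin),
              prcp = rep12(mc@prcp), rh09 = rep12(mc@rh09),
              rh15 = rep12(mc@rh15))
}

# a synthetic station table built from given climatologies
makeStations <- function(lon, lat, elev, climates) {
  stopifnot(length(lon) == length(climates))
  rows <- lapply(seq_along(lon), function(i) {
    mc <- climates[[i]]
    vals <- c(mc@tmax, mc@tmin, mc@prcp, mc@rh09, mc@rh15)
    df <- as.data.frame(as.list(vals))
    names(df) <- as.vector(vapply(c("tmax", "tmin", "prcp", "rh09", "rh15"),
                                  function(v) sprintf("%s%02d", v, 1:12),
                                  character(12)))
    cbind(data.frame(id = paste0("st", i), lon = lon[i], lat = lat[i],
                     elev = elev[i]), df)
  })
  do.call(rbind, rows)
}

writeStationFile <- function(stations, path = tempfile(fileext = ".csv")) {
  utils::write.csv(stations, path, row.names = FALSE, quote = FALSE)
  path
}

# Independent hand computation of EI for a *constant monthly* climate,
# written with its own scalar arithmetic (own trapezoid, own bucket
# recurrence, own stress sums) so it shares no code path with the
# engine.  Weekly rain follows the documented totals convention: each
# week carries its month's total divided by that month's week count.
oracleEi <- function(tmaxM, tminM, prcpM, rh09M, rh15M, p, capacity = 100) {
  trap <- function(x, a, b, c, d) {
    if (x <= a || x >= d) 0
    else if (x < b) (x - a) / (b - a)
    else if (x <= c) 1
    else (d - x) / (d - c)
  }
  tavg <- (tmaxM + tminM) / 2
  monthOfWeek <- floor((1:52 - 0.5) * 12 / 52) + 1
  weeksIn <- tabulate(monthOfWeek, 12)
  rainW <- (prcpM / weeksIn)[monthOfWeek]
  demand <- max(0, 0.8 * tavg) * (1 - (rh09M + rh15M) / 200) * 7
  cap <- p@sm3 + 1
  sm <- numeric(52); carry <- 0
  for (cycle in 1:400) {
    old <- sm
    for (w in 1:52) {
      carry <- carry + (rainW[w] - demand * min(1, carry)) / capacity
      carry <- min(cap, max(0, carry))
      sm[w] <- carry
    }
    if (max(abs(sm - old)) < 1e-13) break
  }
  ti <- trap(tavg, p@dv0, p@dv1, p@dv2, p@dv3)
  mi <- vapply(sm, trap, numeric(1), p@sm0, p@sm1, p@sm2, p@sm3)
  giA <- 100 * sum(ti * mi) / 52
  cs <- min(100, 100 * abs(p@thcs) * 52 * max(0, p@ttcs - tminM))
  hs <- min(100, 100 * abs(p@thhs) * 52 * max(0, tmaxM - p@tths))
  ds <- min(100, 100 * abs(p@hds) * sum(pmax(0, p@smds - sm)))
  ws <- min(100, 100 * abs(p@hws) * sum(pmax(0, sm - p@smws)))
  si <- (1 - cs / 100) * (1 - ds / 100) * (1 - hs / 100) * (1 - ws / 100)
  gen <- max(0, tavg - p@dv0) * 7 * 52 / p@pdd
  ei <- giA * si
  if (gen < 1 || cs >= 100 || ti == 0 || all(mi == 0)) ei <- 0
  ei
}
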