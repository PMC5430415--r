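#' Construct a grid geometry
#'
#' @param lonOrigin,latOrigin south-west corner (degrees).
#' @param cellSize cell edge (degrees).
#' @param nCols,nRows grid dimensions.
#' @return a validated [GridSpec-class] object.
#' @examples
#' GridSpec(98, 18, 0.5, 50, 50)  # a 25 x 25 degree monsoon-gradient domain
#' @export
GridSpec <- function(lonOrigin, latOrigin, cellSize, nCols, nRows) {
  new("GridSpec", lonOrigin = lonOrigin, latOrigin = latOrigin,
      cellSize = cellSize, nCols = as.integer(nCols),
      nRows = as.integer(nRows))
}

sameSpec <- function(a, b) {
  isTRUE(all.equal(a@lonOrigin, b@lonOrigin)) &&
    isTRUE(all.equal(a@latOrigin, b@latOrigin)) &&
    isTRUE(all.equal(a@cellSize, b@cellSize)) &&
    a@nCols == b@nCols && a@nRows == b@nRows
}

#' Construct a gridded climatology
#'
#' @param spec a [GridSpec-class] object.
#' @param tmax,tmin,prcp,rh09,rh15 `nCells x 12` matrices (cells in
#'   row-major order from the south-west corner).
#' @param elevation per-cell elevation (m); default sea level.
#' @param mask per-cell study-region mask; default all cells valid.
#' @return a validated [ClimateGrid-class] object.
#' @export
ClimateGrid <- function(spec, tmax, tmin, prcp, rh09, rh15,
                        elevation = rep(0, nCells(spec)),
                        mask = rep(TRUE, nCells(spec))) {
  new("ClimateGrid", spec = spec,
      tmax = as.matrix(tmax), tmin = as.matrix(tmin),
      prcp = as.matrix(prcp), rh09 = as.matrix(rh09),
      rh15 = as.matrix(rh15),
      elevation = as.numeric(elevation), mask = as.logical(mask))
}

#' Extract one cell's climatology
#'
#' @param grid a [ClimateGrid-class] object.
#' @param cell cell index (row-major from the south-west corner).
#' @return a [MonthlyClimate-class] object.
#' @export
cellClimate <- function(grid, cell) {
  MonthlyClimate(tmax = grid@tmax[cell, ], tmin = grid@tmin[cell, ],
                 prcp = grid@prcp[cell, ], rh09 = grid@rh09[cell, ],
                 rh15 = grid@rh15[cell, ])
}

stationClimateColumns <- function() {
  vars <- c("tmax", "tmin", "prcp", "rh09", "rh15")
  as.vector(vapply(vars, function(v) sprintf("%s%02d", v, 1:12),
                   character(12)))
}

#' Read a station climatology CSV
#'
#' Expected columns: `id`, `lon`, `lat`, `elev`, then the 60 climate
#' columns `tmax01..tmax12`, `tmin01..tmin12`, `prcp01..prcp12`,
#' `rh0901..rh0912`, `rh1501..rh1512`.  Rows violating the climate
#' invariants (tmin above tmax, negative precipitation, humidity outside
#' 0-100, coordinates out of range) are kept but reported by file line
#' number in a warning and in the returned `flagged` attribute.
#'
#' @param path CSV file path.
#' @return a data.frame of stations (one row each), with attribute
#'   `flagged`: a data.frame of `line`, `id`, `problem`.
#' @export
readStationCsv <- function(path) {
  if (!file.exists(path)) stop("station file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  needed <- c("id", "lon", "lat", "elev", stationClimateColumns())
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("station file is missing column(s): ", paste(missing, collapse = ", "))
  }
  numCols <- setdiff(needed, "id")
  for (cn in numCols) {
    if (!is.numeric(df[[cn]])) {
      raw <- df[[cn]]
      val <- suppressWarnings(as.numeric(raw))
      if (anyNA(val) & !anyNA(raw)) {
        bad <- which(is.na(val))[1L]
        stop(sprintf("unparseable number in column %s, line %d: '%s'",
                     cn, bad + 1L, raw[bad]))
      }
      df[[cn]] <- val
    }
  }
  flagged <- data.frame(line = integer(), id = character(),
                        problem = character())
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      probs <- character()
      if (is.na(df$lon[i]) || df$lon[i] < -180 || df$lon[i] > 180 ||
          is.na(df$lat[i]) || df$lat[i] < -90 || df$lat[i] > 90) {
        probs <- c(probs, "coordinates out of range")
      }
      tmx <- as.numeric(df[i, sprintf("tmax%02d", 1:12)])
      tmn <- as.numeric(df[i, sprintf("tmin%02d", 1:12)])
      if (any(tmx < tmn)) probs <- c(probs, "tmin exceeds tmax")
      if (any(as.numeric(df[i, sprintf("prcp%02d", 1:12)]) < 0)) {
        probs <- c(probs, "negative precipitation")
      }
      rh <- as.numeric(df[i, c(sprintf("rh09%02d", 1:12),
                               sprintf("rh15%02d", 1:12))])
      if (any(rh < 0 | rh > 100)) probs <- c(probs, "humidity outside [0,100]")
      if (length(probs)) {
        flagged <- rbind(flagged, data.frame(
          line = i + 1L, id = as.character(df$id[i]),
          problem = paste(probs, collapse = "; ")
        ))
      }
    }
  }
  if (nrow(flagged)) {
    warning(sprintf("%d station row(s) violate climate invariants (lines %s)",
                    nrow(flagged), paste(flagged$line, collapse = ", ")))
  }
  attr(df, "flagged") <- flagged
  df
}

#' Interpolate station climatologies to a grid (IDW + lapse rate)
#'
#' Inverse-distance-weighted interpolation over the `k` nearest
#' stations (great-circle distances), with an elevation adjustment for
#' the temperature fields: station temperatures are reduced to sea level
#' with the lapse rate, interpolated, then re-elevated to the cell
#' elevation.  A cell lying on a station (distance below ~1 m) takes the
#' station values exactly.
#'
#' @param stations station data.frame as returned by [readStationCsv()].
#' @param spec target [GridSpec-class].
#' @param power IDW exponent (> 0; weights are distance^-power).
#' @param kNeighbors number of nearest stations used per cell (clamped
#'   to the number of stations, with a warning).
#' @param lapseRate temperature lapse rate (degrees C per km; default 6.5).
#' @param gridElevation per-cell elevation (m); default sea level.
#' @return a [ClimateGrid-class] object (mask all TRUE).
#' @export
idwInterpolate <- function(stations, spec, power = 2, kNeighbors = 12L,
                           lapseRate = 6.5,
                           gridElevation = rep(0, nCells(spec))) {
  ns <- nrow(stations)
  if (is.null(ns) || ns < 1L) stop("at least one station is required")
  if (power <= 0) stop("power must be > 0")
  if (kNeighbors < 1L) stop("kNeighbors must be >= 1")
  if (kNeighbors > ns) {
    warning(sprintf("kNeighbors = %d exceeds the %d stations; clamped",
                    kNeighbors, ns))
    kNeighbors <- ns
  }
  n <- nCells(spec)
  if (length(gridElevation) != n) stop("gridElevation must have one value per cell")
  cc <- cellCenters(spec)
  dist <- geosphere::distm(cbind(cc$lon, cc$lat),
                           cbind(stations$lon, stations$lat),
                           fun = geosphere::distHaversine)

  vars <- c("tmax", "tmin", "prcp", "rh09", "rh15")
  fields <- lapply(vars, function(v) {
    m <- as.matrix(stations[, sprintf("%s%02d", v, 1:12)])
    if (v %in% c("tmax", "tmin")) m <- m + lapseRate * stations$elev / 1000
    m
  })
  names(fields) <- vars

  out <- lapply(vars, function(v) matrix(0, n, 12L))
  names(out) <- vars
  for (i in seq_len(n)) {
    d <- dist[i, ]
    hit <- which(d < 1)
    if (length(hit)) {
      for (v in vars) out[[v]][i, ] <- fields[[v]][hit[1L], ]
      next
    }
    nb <- order(d)[seq_len(kNeighbors)]
    w <- d[nb]^(-power)
    w <- w / sum(w)
    for (v in vars) {
      out[[v]][i, ] <- as.numeric(w %*% fields[[v]][nb, , drop = FALSE])
    }
  }
  adj <- lapseRate * gridElevation / 1000
  out$tmax <- out$tmax - adj
  out$tmin <- out$tmin - adj
  # the convex IDW combination keeps RH within the station range, but
  # float rounding can graze the bounds
  out$rh09 <- pmin(pmax(out$rh09, 0), 100)
  out$rh15 <- pmin(pmax(out$rh15, 0), 100)
  out$prcp <- pmax(out$prcp, 0)
  ClimateGrid(spec, tmax = out$tmax, tmin = out$tmin, prcp = out$prcp,
              rh09 = out$rh09, rh15 = out$rh15,
              elevation = gridElevation)
}

#' Calibrate a future climate by additive GCM anomalies
#'
#' The delta (anomaly) method: for every cell, variable and month,
#' `future = observed + (GCM future - GCM baseline)`.  Adding the
#' GCM's own change to the observed baseline avoids the GCM's bias in
#' absolute values.  Precipitation and humidity are floored at 0 and
#' humidity capped at 100 after the shift; any tmax/tmin inversions the
#' deltas introduce are repaired by swapping, with a message giving the
#' count.
#'
#' @param baselineObs observed baseline [ClimateGrid-class].
#' @param gcmBaseline,gcmFuture GCM output for the baseline and target
#'   periods, on the same [GridSpec-class].
#' @return the calibrated future [ClimateGrid-class].
#' @export
applyGcmDelta <- function(baselineObs, gcmBaseline, gcmFuture) {
  if (!sameSpec(baselineObs@spec, gcmBaseline@spec) ||
      !sameSpec(baselineObs@spec, gcmFuture@spec)) {
    stop("all three grids must share one GridSpec")
  }
  tmax <- baselineObs@tmax + (gcmFuture@tmax - gcmBaseline@tmax)
  tmin <- baselineObs@tmin + (gcmFuture@tmin - gcmBaseline@tmin)
  prcp <- pmax(baselineObs@prcp + (gcmFuture@prcp - gcmBaseline@prcp), 0)
  rh09 <- pmin(pmax(baselineObs@rh09 + (gcmFuture@rh09 - gcmBaseline@rh09), 0), 100)
  rh15 <- pmin(pmax(baselineObs@rh15 + (gcmFuture@rh15 - gcmBaseline@rh15), 0), 100)
  swap <- tmax < tmin
  if (any(swap)) {
    message(sprintf("applyGcmDelta: repaired %d tmax/tmin inversion(s) by swapping",
                    sum(swap)))
    lo <- pmin(tmax, tmin)
    hi <- pmax(tmax, tmin)
    tmax <- hi; tmin <- lo
  }
  ClimateGrid(baselineObs@spec, tmax = tmax, tmin = tmin, prcp = prcp,
              rh09 = rh09, rh15 = rh15,
              elevation = baselineObs@elevation, mask = baselineObs@mask)
}

# Evaluate code with a private RNG stream so grid generation is
# deterministic without disturbing the caller's random state.
withLocalSeed <- function(seed, code) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Tunable constants of the synthetic climate generator
#'
#' One place for the spatial-structure constants of
#' [generateSyntheticRegion()], so experiments can tighten or relax the
#' emulated geography.  Defaults emulate a subtropical-to-temperate
#' monsoon domain: mean temperature falling 0.7 degrees C per degree
#' latitude northward, seasonal amplitude growing northward, a
#' high-elevation plateau block in the north-west cooled by the lapse
#' rate, annual precipitation decaying from the south-east (wet, ~2000
#' mm) to the north-west (arid, < 100 mm) with a July-peaked monsoon
#' share, and humidity tied to local wetness.
#'
#' @param tMeanSouth annual mean temperature at the southern edge (degrees C).
#' @param tLatSlope cooling per degree latitude northward (degrees C).
#' @param ampBase,ampLatSlope seasonal (July-peak) amplitude at the
#'   southern edge and its growth per degree latitude.
#' @param diurnalWet,diurnalDry diurnal temperature range (degrees C) in
#'   fully wet / fully dry cells.
#' @param lapseRate lapse rate (degrees C per km).
#' @param plateauElev plateau elevation (m); `baseElev` elsewhere.
#' @param baseElev lowland elevation (m).
#' @param annualPrcpScale annual precipitation (mm) at wetness 1.
#' @param monsoonShare amplitude of the July-peaked monthly
#'   precipitation share (0 = uniform).
#' @param noiseTemp,noiseWet,noiseElev spatial-noise scales (degrees C,
#'   wetness fraction, m).
#' @param futureTmaxDelta,futureTminDelta uniform warming applied to the
#'   future scenario (degrees C).
#' @param futurePrcpFactor multiplicative precipitation change applied
#'   January-September in the future scenario.
#' @return a named list of constants.
#' @export
syntheticRegionConfig <- function(tMeanSouth = 25, tLatSlope = 0.7,
                                  ampBase = 4, ampLatSlope = 0.55,
                                  diurnalWet = 8, diurnalDry = 13,
                                  lapseRate = 6.5,
                                  plateauElev = 4500, baseElev = 150,
                                  annualPrcpScale = 1500,
                                  monsoonShare = 0.9,
                                  noiseTemp = 0.6, noiseWet = 0.06,
                                  noiseElev = 120,
                                  futureTmaxDelta = 1.0,
                                  futureTminDelta = 1.2,
                                  futurePrcpFactor = 1.05) {
  as.list(environment())
}

# smooth 0..1 ramp used for the plateau edges
smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# smooth random field: a handful of seeded cosine modes over unit coords
cosineNoiseField <- function(u, v, nModes = 6L) {
  z <- numeric(length(u))
  for (j in seq_len(nModes)) {
    f <- stats::runif(2, 0.5, 3)
    ph <- stats::runif(1, 0, 2 * pi)
    a <- stats::rnorm(1, 0, 1 / nModes)
    z <- z + a * cos(2 * pi * (f[1] * u + f[2] * v) + ph)
  }
  z
}

#' Generate a synthetic monsoon-gradient climate grid
#'
#' A deterministic, seeded stand-in for an East-Asian style climatology:
#' temperature falls northward and over the high plateau block,
#' seasonality (July peak) strengthens northward, precipitation decays
#' along the south-east to north-west monsoon axis with a summer-heavy
#' monthly share, and humidity follows local wetness.  The `"future"`
#' scenario applies a uniform +1.0 degrees C to tmax and +1.2 degrees C
#' to tmin and raises January-September precipitation by 5%; humidity
#' is left unchanged.  The same `(spec, seed)` always yields
#' bit-identical grids, and the current/future pair differs only by
#' those deltas.
#'
#' @param spec target [GridSpec-class].
#' @param seed integer seed for the smooth spatial noise.
#' @param scenario `"current"` or `"future"`.
#' @param config constants from [syntheticRegionConfig()].
#' @return a [ClimateGrid-class] object.
#' @examples
#' g <- generateSyntheticRegion(GridSpec(98, 18, 1, 10, 10), seed = 1)
#' @export
generateSyntheticRegion <- function(spec, seed,
                                    scenario = c("current", "future"),
                                    config = syntheticRegionConfig()) {
  scenario <- match.arg(scenario)
  cfg <- config
  cc <- cellCenters(spec)
  lonSpan <- spec@nCols * spec@cellSize
  latSpan <- spec@nRows * spec@cellSize
  u <- (cc$lon - spec@lonOrigin) / lonSpan   # 0 west .. 1 east
  v <- (cc$lat - spec@latOrigin) / latSpan   # 0 south .. 1 north

  noise <- withLocalSeed(seed, list(
    temp = cosineNoiseField(u, v),
    wet = cosineNoiseField(u, v),
    elev = cosineNoiseField(u, v)
  ))

  # elevation: high plateau in the north-west quadrant, lowland elsewhere
  plateau <- smoothstep((0.35 - u) / 0.1) * smoothstep((v - 0.35) / 0.1)
  elev <- pmax(0, cfg$baseElev + (cfg$plateauElev - cfg$baseElev) * plateau +
                 cfg$noiseElev * noise$elev)

  # wetness along the SE -> NW monsoon axis
  nw <- (v + (1 - u)) / 2
  wet <- pmin(1.3, pmax(0.03, 1.3 - 1.25 * nw + cfg$noiseWet * noise$wet))

  latN <- cc$lat - spec@latOrigin
  tbar <- cfg$tMeanSouth - cfg$tLatSlope * latN -
    cfg$lapseRate * elev / 1000 + cfg$noiseTemp * noise$temp
  amp <- cfg$ampBase + cfg$ampLatSlope * latN
  diurnal <- cfg$diurnalWet + (cfg$diurnalDry - cfg$diurnalWet) * (1 - wet / 1.3)

  months <- 1:12
  seasonal <- cos(2 * pi * (months - 7) / 12)          # +1 in July
  tavg <- outer(tbar, rep(1, 12)) + outer(amp, seasonal)
  tmax <- tavg + diurnal / 2
  tmin <- tavg - diurnal / 2

  share <- 1 + cfg$monsoonShare * seasonal
  share <- share / sum(share)
  prcp <- outer(cfg$annualPrcpScale * wet, share)

  rhMean <- pmin(92, pmax(22, 35 + 48 * wet))
  rhMonth <- outer(rhMean, rep(1, 12)) + outer(rep(6, length(rhMean)), seasonal)
  rh09 <- pmin(pmax(rhMonth + 7, 5), 100)
  rh15 <- pmin(pmax(rhMonth - 7, 5), 100)

  if (scenario == "future") {
    tmax <- tmax + cfg$futureTmaxDelta
    tmin <- tmin + cfg$futureTminDelta
    prcp[, 1:9] <- prcp[, 1:9] * cfg$futurePrcpFactor
  }

  ClimateGrid(spec, tmax = tmax, tmin = tmin, prcp = prcp,
              rh09 = rh09, rh15 = rh15, elevation = elev)
}

#' Write / read a climate grid as long-format CSV
#'
#' Long format: columns `cell`, `lon`, `lat`, `variable`, `month`,
#' `value`, preceded by `#`-prefixed header lines carrying the grid
#' geometry.  Elevation and mask travel as variables `elev` and `mask`
#' with month 0.  Values are printed at full precision so the round trip
#' is bit-exact.
#'
#' @param grid a [ClimateGrid-class] object.
#' @param path CSV file path.
#' @return `readClimateGridCsv` returns the [ClimateGrid-class];
#'   `writeClimateGridCsv` returns `path` invisibly.
#' @export
writeClimateGridCsv <- function(grid, path) {
  spec <- grid@spec
  cc <- cellCenters(spec)
  vars <- c("tmax", "tmin", "prcp", "rh09", "rh15")
  n <- nCells(spec)
  rows <- do.call(rbind, lapply(vars, function(v) {
    m <- slot(grid, v)
    data.frame(cell = rep(cc$cell, 12L), lon = rep(cc$lon, 12L),
               lat = rep(cc$lat, 12L), variable = v,
               month = rep(1:12, each = n), value = as.numeric(m))
  }))
  extra <- rbind(
    data.frame(cell = cc$cell, lon = cc$lon, lat = cc$lat,
               variable = "elev", month = 0L, value = grid@elevation),
    data.frame(cell = cc$cell, lon = cc$lon, lat = cc$lat,
               variable = "mask", month = 0L, value = as.numeric(grid@mask))
  )
  rows <- rbind(rows, extra)
  header <- c(
    sprintf("# lon_origin: %s", formatC(spec@lonOrigin, digits = 17, format = "g")),
    sprintf("# lat_origin: %s", formatC(spec@latOrigin, digits = 17, format = "g")),
    sprintf("# cell_size: %s", formatC(spec@cellSize, digits = 17, format = "g")),
    sprintf("# n_cols: %d", spec@nCols),
    sprintf("# n_rows: %d", spec@nRows)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("cell,lon,lat,variable,month,value", con)
  writeLines(sprintf("%d,%s,%s,%s,%d,%s",
                     rows$cell,
                     formatC(rows$lon, digits = 17, format = "g"),
                     formatC(rows$lat, digits = 17, format = "g"),
                     rows$variable, rows$month,
                     formatC(rows$value, digits = 17, format = "g")), con)
  invisible(path)
}

#' @rdname writeClimateGridCsv
#' @export
readClimateGridCsv <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getNum <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("grid file header is missing ", key)
    as.numeric(sub(".*: *", "", ln[1L]))
  }
  spec <- GridSpec(getNum("lon_origin"), getNum("lat_origin"),
                   getNum("cell_size"), getNum("n_cols"), getNum("n_rows"))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  n <- nCells(spec)
  pick <- function(v) {
    m <- matrix(0, n, 12L)
    sub <- df[df$variable == v, ]
    m[cbind(sub$cell, sub$month)] <- sub$value
    m
  }
  elev <- df[df$variable == "elev", ]
  mask <- df[df$variable == "mask", ]
  ClimateGrid(spec, tmax = pick("tmax"), tmin = pick("tmin"),
              prcp = pick("prcp"), rh09 = pick("rh09"), rh15 = pick("rh15"),
              elevation = elev$value[order(elev$cell)],
              mask = mask$value[order(mask$cell)] != 0)
}
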