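eiClassLevels <- function() {
  c("unfavourable", "marginal", "favourable", "highly_favourable")
}

#' Classify Ecoclimatic Index values into favourability classes
#'
#' The four-class rule: `EI = 0` unfavourable, `0 < EI <= 10` marginally
#' favourable, `10 < EI <= 20` favourable, `EI > 20` highly favourable.
#' The boundary value 20 itself is favourable (the class definitions
#' partition the axis at 10 and 20 with closed upper ends).
#'
#' @param ei numeric EI values in `[0, 100]` (NA passes through).
#' @return factor with levels `unfavourable`, `marginal`, `favourable`,
#'   `highly_favourable`.
#' @examples
#' classifyEi(c(0, 5, 10, 10.01, 20, 25))
#' @export
classifyEi <- function(ei) {
  if (any(ei < 0 | ei > 100, na.rm = TRUE)) {
    stop("ei values must lie in [0, 100]")
  }
  lv <- eiClassLevels()
  out <- rep(NA_character_, length(ei))
  ok <- !is.na(ei)
  out[ok & ei == 0] <- lv[1L]
  out[ok & ei > 0 & ei <= 10] <- lv[2L]
  out[ok & ei > 10 & ei <= 20] <- lv[3L]
  out[ok & ei > 20] <- lv[4L]
  factor(out, levels = lv)
}

#' Run the engine over every cell of a climate grid
#'
#' Vectorized equivalent of calling [runLocation()] cell by cell;
#' returns the gridded suitability product with per-cell EI,
#' favourability class, limiting-condition flags and cell areas.
#'
#' @param grid a [ClimateGrid-class] object.
#' @param p a [SpeciesParams-class] object.
#' @param capacity soil bucket capacity (mm).
#' @param evapK evaporative demand coefficient.
#' @return a [SuitabilityGrid-class] object.
#' @export
runGrid <- function(grid, p, capacity = 100, evapK = 0.8) {
  stopifnot(is(grid, "ClimateGrid"), is(p, "SpeciesParams"))
  v <- validateParams(p)
  if (length(v)) stop("invalid parameter set: ", paste(v, collapse = "; "))
  res <- runCellsMatrix(grid, p, capacity = capacity, evapK = evapK)
  n <- nCells(grid@spec)
  ei <- rep(NA_real_, n)
  ei[res$cell] <- res$ei
  flags <- matrix(FALSE, n, 4L,
                  dimnames = list(NULL, c("GEN_LT_1", "CS_GE_100",
                                          "TI_ZERO", "MI_ZERO")))
  flags[res$cell, ] <- as.matrix(res[, c("GEN_LT_1", "CS_GE_100",
                                         "TI_ZERO", "MI_ZERO")])
  new("SuitabilityGrid",
      spec = grid@spec, ei = ei, eiClass = classifyEi(ei), flags = flags,
      cellArea = cellAreas(grid@spec), mask = grid@mask, results = res)
}

#' Per-class area summary
#'
#' Sums cell areas by favourability class over the study region (or a
#' sub-region) and reports each class's share of the region total and of
#' the potential distribution, defined as the union of the three
#' favourable classes (everything but unfavourable).
#'
#' @param grid a [SuitabilityGrid-class] object.
#' @param region optional integer vector of cell indices restricting
#'   the summary (a region-mask entry).
#' @return data.frame with columns `class`, `area_km2`, `pct_region`,
#'   `pct_potential` (`NA` percentages when the denominator is empty).
#' @export
areaSummary <- function(grid, region = NULL) {
  cells <- which(gridMask(grid) & !is.na(grid@ei))
  if (!is.null(region)) cells <- intersect(cells, region)
  lv <- eiClassLevels()
  area <- vapply(lv, function(cl) {
    sum(grid@cellArea[cells][grid@eiClass[cells] == cl])
  }, numeric(1))
  total <- sum(area)
  potential <- sum(area[lv != "unfavourable"])
  data.frame(
    class = factor(lv, levels = lv),
    area_km2 = as.numeric(area),
    pct_region = if (total > 0) 100 * area / total else rep(NA_real_, 4L),
    pct_potential = ifelse(lv == "unfavourable", NA_real_,
                           if (potential > 0) 100 * area / potential
                           else NA_real_),
    row.names = NULL
  )
}

#' Limiting-condition cell masks
#'
#' Returns, for each of the four EI-zeroing conditions (generations
#' below 1, cold stress at 100, all-year zero Temperature Index,
#' all-year zero Moisture Index), the set of cells it affects.  A cell
#' may satisfy several conditions and then appears in several masks.
#'
#' @param grid a [SuitabilityGrid-class] object.
#' @return named list of integer cell-index vectors
#'   (`GEN_LT_1`, `CS_GE_100`, `TI_ZERO`, `MI_ZERO`).
#' @export
limitingFactorMap <- function(grid) {
  f <- limitingFlags(grid)
  lapply(stats::setNames(colnames(f), colnames(f)),
         function(cn) which(f[, cn]))
}

#' Impact index of a limiting condition in a region
#'
#' An integer 0-10 proportional to the fraction of the region's area
#' affected by the condition: `round(10 * affectedArea / regionArea)`
#' with half-up rounding.  Areas, not cell counts, are used.
#'
#' @param affected integer cell indices affected by the condition.
#' @param region integer cell indices of the region (non-empty).
#' @param spec the [GridSpec-class] supplying cell areas (or any object
#'   with a `cellAreas` method).
#' @return integer in 0..10.
#' @examples
#' sp <- GridSpec(100, 30, 1, 3, 1)   # 3 equal-latitude cells
#' impactIndex(1L, 1:3, sp)           # one of three -> round(10/3) = 3
#' @export
impactIndex <- function(affected, region, spec) {
  if (length(region) == 0L) stop("region must be non-empty")
  areas <- cellAreas(spec)
  frac <- sum(areas[intersect(affected, region)]) / sum(areas[region])
  as.integer(floor(10 * frac + 0.5))
}

#' Per-cell EI change between two scenarios
#'
#' @param current,future [SuitabilityGrid-class] objects on one
#'   [GridSpec-class].
#' @return list with `delta` (per-cell `future - current`, NA outside
#'   the common mask) and `summary` (data.frame: `maxIncrease`,
#'   `maxDecrease`, `mean` over unmasked cells).
#' @export
eiDifference <- function(current, future) {
  if (!sameSpec(current@spec, future@spec)) {
    stop("grids must share one GridSpec")
  }
  delta <- future@ei - current@ei
  ok <- gridMask(current) & gridMask(future) & !is.na(delta)
  delta[!ok] <- NA_real_
  d <- delta[ok]
  list(
    delta = delta,
    summary = data.frame(maxIncrease = max(d), maxDecrease = min(d),
                         mean = mean(d))
  )
}

#' Latitudinal range shift of a favourability class
#'
#' The area-weighted latitude centroid of the class's cells in the
#' future scenario minus the same centroid under the current scenario;
#' positive values are northward shifts.  Centroids are exact under
#' translation of a class block.  When the class is absent from either
#' scenario (within the region) the shift is undefined and `NA` is
#' returned with a warning.
#'
#' @param current,future [SuitabilityGrid-class] objects on one
#'   [GridSpec-class].
#' @param class one of `"marginal"`, `"favourable"`, `"highly_favourable"`
#'   (or `"unfavourable"`).
#' @param region optional integer cell indices restricting the
#'   computation.
#' @return degrees latitude (positive = northward), or `NA` when
#'   undefined.
#' @export
rangeShift <- function(current, future, class = "highly_favourable",
                       region = NULL) {
  if (!sameSpec(current@spec, future@spec)) {
    stop("grids must share one GridSpec")
  }
  class <- match.arg(class, eiClassLevels())
  lat <- cellCenters(current@spec)$lat
  centroid <- function(g) {
    cells <- which(gridMask(g) & !is.na(g@ei) & g@eiClass == class)
    if (!is.null(region)) cells <- intersect(cells, region)
    if (length(cells) == 0L) return(NA_real_)
    w <- g@cellArea[cells]
    sum(w * lat[cells]) / sum(w)
  }
  a <- centroid(current); b <- centroid(future)
  if (is.na(a) || is.na(b)) {
    warning(sprintf("class '%s' absent from %s scenario; shift undefined",
                    class,
                    paste(c("current", "future")[c(is.na(a), is.na(b))],
                          collapse = " and ")))
    return(NA_real_)
  }
  b - a
}

# point-in-cell assignment: a point on an interior cell edge belongs to
# the south-west cell (nearest-center rule with south-west tie-break)
pointToCell <- function(spec, lon, lat) {
  ix <- (lon - spec@lonOrigin) / spec@cellSize
  iy <- (lat - spec@latOrigin) / spec@cellSize
  outside <- ix < 0 | ix > spec@nCols | iy < 0 | iy > spec@nRows
  col <- pmin(spec@nCols, pmax(1L, ceiling(ix)))
  row <- pmin(spec@nRows, pmax(1L, ceiling(iy)))
  cell <- (row - 1L) * spec@nCols + col
  cell[outside] <- NA_integer_
  as.integer(cell)
}

#' Read an occurrence-record CSV
#'
#' Columns: `lon`, `lat` (decimal degrees), `source` (e.g. CABI or
#' literature) and `role` (`modelling` or `validation`).
#'
#' @param path CSV file path.
#' @return data.frame of occurrence records.
#' @export
readOccurrenceCsv <- function(path) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("lon", "lat", "source", "role"), names(df))
  if (length(missing)) {
    stop("occurrence file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("occurrence file contains no records")
  bad <- which(df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90)
  if (length(bad)) {
    stop("occurrence coordinates out of range at data row(s): ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Validate occurrence records against a suitability grid
#'
#' Assigns each point to its containing cell and checks whether the
#' predicted class there is suitable (anything but unfavourable).
#' Points outside the grid extent or in masked-out cells are excluded
#' from the denominator with a warning.
#'
#' @param points data.frame with `lon` and `lat` columns (typically the
#'   validation subset of [readOccurrenceCsv()] output).
#' @param grid a [SuitabilityGrid-class] object.
#' @return list with `percentSuitable` (0-100), `nUsed`, `nExcluded`,
#'   and `table`: per-point `lon`, `lat`, `cell`, `ei`, `class`,
#'   `suitable`.
#' @export
validateOccurrences <- function(points, grid) {
  stopifnot(is.data.frame(points), all(c("lon", "lat") %in% names(points)))
  if (nrow(points) == 0L) stop("no occurrence points supplied")
  cell <- pointToCell(grid@spec, points$lon, points$lat)
  usable <- !is.na(cell)
  usable[usable] <- gridMask(grid)[cell[usable]] &
    !is.na(grid@ei[cell[usable]])
  if (!any(usable)) stop("no occurrence point falls inside the grid")
  nExcluded <- sum(!usable)
  if (nExcluded > 0) {
    warning(sprintf("%d occurrence point(s) outside the grid extent or mask; excluded",
                    nExcluded))
  }
  tab <- data.frame(
    lon = points$lon, lat = points$lat, cell = cell,
    ei = ifelse(usable, grid@ei[cell], NA_real_),
    class = factor(NA_character_, levels = eiClassLevels()),
    suitable = NA
  )
  tab$class[usable] <- grid@eiClass[cell[usable]]
  tab$suitable[usable] <- tab$class[usable] != "unfavourable"
  list(
    percentSuitable = 100 * sum(tab$suitable[usable]) / sum(usable),
    nUsed = sum(usable),
    nExcluded = nExcluded,
    table = tab
  )
}

#' Latitude-band regions for a grid
#'
#' A synthetic stand-in for administrative regions: splits the grid
#' into `n` equal latitude bands named `band_1` (southernmost) to
#' `band_n`.  Useful for impact-index and range-shift summaries on
#' synthetic grids.
#'
#' @param spec a [GridSpec-class] object.
#' @param n number of bands.
#' @return named list of integer cell-index vectors (a region mask).
#' @export
latBandRegions <- function(spec, n = 5L) {
  row <- rep(seq_len(spec@nRows), each = spec@nCols)
  band <- pmin(n, ceiling(row * n / spec@nRows))
  split(seq_len(nCells(spec)), paste0("band_", band))[paste0("band_", seq_len(n))]
}
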