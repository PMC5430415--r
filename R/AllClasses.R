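#' @import methods
NULL

#' Species parameter set for the ecoclimatic engine
#'
#' Holds the 17 physiological parameters driving the weekly growth and
#' stress model: the temperature response thresholds \code{dv0 < dv1 <=
#' dv2 < dv3} (degrees C), the soil-moisture response thresholds
#' \code{sm0 < sm1 <= sm2 <= sm3} (fractions of bucket capacity), four
#' threshold/rate stress pairs (cold, heat, dry, wet), and the
#' degree-day total \code{pdd} required above \code{dv0} to complete one
#' generation.  Stress rates are stored signed: cold and dry rates are
#' non-positive, heat and wet rates non-negative; accumulation uses their
#' magnitudes.
#'
#' @slot dv0,dv1,dv2,dv3 numeric(1). Temperature response thresholds (degrees C):
#'   lower threshold, lower optimum, upper optimum, upper threshold.
#' @slot sm0,sm1,sm2,sm3 numeric(1). Soil-moisture response thresholds
#'   (fraction of bucket capacity; values above 1 express waterlogging).
#' @slot ttcs numeric(1). Cold stress temperature threshold (degrees C, on weekly minimum).
#' @slot thcs numeric(1). Cold stress rate (per week, <= 0).
#' @slot tths numeric(1). Heat stress temperature threshold (degrees C, on weekly maximum).
#' @slot thhs numeric(1). Heat stress rate (per week, >= 0).
#' @slot smds numeric(1). Dry stress soil-moisture threshold (fraction).
#' @slot hds numeric(1). Dry stress rate (per week, <= 0).
#' @slot smws numeric(1). Wet stress soil-moisture threshold (fraction).
#' @slot hws numeric(1). Wet stress rate (per week, >= 0).
#' @slot pdd numeric(1). Degree-days above \code{dv0} for one generation.
#' @slot pddEnabled logical(1). \code{FALSE} disables the generation
#'   constraint entirely (used by templates that print PDD = 0).
#'
#' @seealso [defaultFornicatusParams()], [wetTropicalTemplate()],
#'   [validateParams()], [readParamsFile()]
#' @export
setClass("SpeciesParams",
  representation(
    dv0 = "numeric", dv1 = "numeric", dv2 = "numeric", dv3 = "numeric",
    sm0 = "numeric", sm1 = "numeric", sm2 = "numeric", sm3 = "numeric",
    ttcs = "numeric", thcs = "numeric",
    tths = "numeric", thhs = "numeric",
    smds = "numeric", hds = "numeric",
    smws = "numeric", hws = "numeric",
    pdd = "numeric", pddEnabled = "logical"
  )
)

setValidity("SpeciesParams", function(object) {
  v <- validateParams(object)
  if (length(v) == 0L) TRUE else v
})

#' Regular longitude/latitude grid geometry
#'
#' A regular grid of square (in degrees) cells.  Cell centers sit at
#' \code{origin + (i + 0.5) * cellSize}; cells are indexed row-major
#' starting at the south-west corner (row 1 = southernmost row).  Cell
#' area in km^2 is \code{(111.32 * cellSize)^2 * cos(latCenter)}.
#'
#' @slot lonOrigin,latOrigin numeric(1). South-west corner of the grid (degrees).
#' @slot cellSize numeric(1). Cell edge length (degrees), > 0.
#' @slot nCols,nRows integer(1). Grid dimensions, > 0.
#' @export
setClass("GridSpec",
  representation(
    lonOrigin = "numeric", latOrigin = "numeric",
    cellSize = "numeric", nCols = "integer", nRows = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0) {
    msg <- c(msg, "cellSize must be a single positive number")
  }
  if (length(object@nCols) != 1L || object@nCols < 1L) {
    msg <- c(msg, "nCols must be >= 1")
  }
  if (length(object@nRows) != 1L || object@nRows < 1L) {
    msg <- c(msg, "nRows must be >= 1")
  }
  if (!is.finite(object@lonOrigin) || !is.finite(object@latOrigin)) {
    msg <- c(msg, "grid origin must be finite")
  }
  if (length(msg) == 0L) TRUE else msg
})

#' Monthly climatology for one location
#'
#' Twelve-month climate normals: average maximum and minimum temperature,
#' monthly precipitation total, and relative humidity observed at 09:00
#' and 15:00.
#'
#' @slot tmax,tmin numeric(12). Monthly mean daily maximum/minimum temperature (degrees C).
#' @slot prcp numeric(12). Monthly precipitation total (mm).
#' @slot rh09,rh15 numeric(12). Relative humidity at 09:00 / 15:00 (percent).
#' @export
setClass("MonthlyClimate",
  representation(
    tmax = "numeric", tmin = "numeric", prcp = "numeric",
    rh09 = "numeric", rh15 = "numeric"
  )
)

setValidity("MonthlyClimate", function(object) {
  msg <- character()
  for (s in c("tmax", "tmin", "prcp", "rh09", "rh15")) {
    x <- slot(object, s)
    if (length(x) != 12L || !all(is.finite(x))) {
      msg <- c(msg, sprintf("%s must hold 12 finite values", s))
    }
  }
  if (length(msg) == 0L) {
    if (any(object@tmax < object@tmin)) {
      msg <- c(msg, "tmax must be >= tmin in every month")
    }
    if (any(object@prcp < 0)) msg <- c(msg, "prcp must be >= 0")
    if (any(object@rh09 < 0 | object@rh09 > 100) ||
        any(object@rh15 < 0 | object@rh15 > 100)) {
      msg <- c(msg, "relative humidity must lie in [0, 100]")
    }
  }
  if (length(msg) == 0L) TRUE else msg
})

#' Gridded monthly climatology
#'
#' Per-cell monthly climate normals on a [GridSpec].  Each climate slot
#' is an \code{nCells x 12} matrix in row-major (south-west first) cell
#' order.  \code{elevation} is per-cell elevation in metres; \code{mask}
#' flags the cells considered part of the study region.
#'
#' @slot spec [GridSpec] geometry.
#' @slot tmax,tmin,prcp,rh09,rh15 matrix. \code{nCells x 12} climate fields.
#' @slot elevation numeric. Per-cell elevation (m).
#' @slot mask logical. Per-cell validity mask.
#' @export
setClass("ClimateGrid",
  representation(
    spec = "GridSpec",
    tmax = "matrix", tmin = "matrix", prcp = "matrix",
    rh09 = "matrix", rh15 = "matrix",
    elevation = "numeric", mask = "logical"
  )
)

setValidity("ClimateGrid", function(object) {
  msg <- character()
  n <- nCells(object@spec)
  for (s in c("tmax", "tmin", "prcp", "rh09", "rh15")) {
    m <- slot(object, s)
    if (!is.numeric(m) || nrow(m) != n || ncol(m) != 12L) {
      msg <- c(msg, sprintf("%s must be a numeric %d x 12 matrix", s, n))
    }
  }
  if (length(object@elevation) != n) {
    msg <- c(msg, "elevation must have one value per cell")
  }
  if (length(object@mask) != n || anyNA(object@mask)) {
    msg <- c(msg, "mask must be logical with one value per cell, no NA")
  }
  if (length(msg) == 0L) {
    keep <- which(object@mask)
    if (length(keep)) {
      bad <- keep[!apply(
        cbind(
          object@tmax[keep, , drop = FALSE] >= object@tmin[keep, , drop = FALSE],
          object@prcp[keep, , drop = FALSE] >= 0,
          object@rh09[keep, , drop = FALSE] >= 0,
          object@rh09[keep, , drop = FALSE] <= 100,
          object@rh15[keep, , drop = FALSE] >= 0,
          object@rh15[keep, , drop = FALSE] <= 100
        ), 1L, all
      )]
      if (length(bad)) {
        msg <- c(msg, sprintf(
          "%d unmasked cell(s) violate climate invariants (first: cell %d)",
          length(bad), bad[1L]
        ))
      }
    }
  }
  if (length(msg) == 0L) TRUE else msg
})

#' Annual engine result for one location
#'
#' All annual indices for a single cell: the Annual Growth Index
#' \code{giA} (0-100), the four stress accumulations (0-100), the Annual
#' Stress Index \code{si} (0-1), degree-days above \code{dv0} and the
#' implied number of generations, the Ecoclimatic Index \code{ei}
#' (0-100), and the limiting-condition flags that forced EI to zero
#' (subset of \code{GEN_LT_1}, \code{CS_GE_100}, \code{TI_ZERO},
#' \code{MI_ZERO}).
#'
#' @slot giA numeric(1). Annual Growth Index, 0-100.
#' @slot cs,hs,ds,ws numeric(1). Annual cold/heat/dry/wet stress, 0-100.
#' @slot si numeric(1). Annual Stress Index, 0-1.
#' @slot ddAnnual numeric(1). Degree-days above dv0.
#' @slot generations numeric(1). ddAnnual / pdd (Inf disabled check never occurs;
#'   NA when the generation constraint is disabled).
#' @slot ei numeric(1). Ecoclimatic Index, 0-100.
#' @slot limitingFlags character. Satisfied limiting conditions (possibly several).
#' @slot weekly data.frame. Weekly diagnostic series (week, tavg, tmin,
#'   tmax, rain, sm, ti, mi, gi).
#' @export
setClass("CellResult",
  representation(
    giA = "numeric", cs = "numeric", hs = "numeric", ds = "numeric",
    ws = "numeric", si = "numeric", ddAnnual = "numeric",
    generations = "numeric", ei = "numeric", limitingFlags = "character",
    weekly = "data.frame"
  )
)

setValidity("CellResult", function(object) {
  msg <- character()
  if (object@ei < 0 || object@ei > 100) msg <- c(msg, "ei must lie in [0, 100]")
  for (s in c("cs", "hs", "ds", "ws")) {
    x <- slot(object, s)
    if (x < 0 || x > 100) msg <- c(msg, sprintf("%s must lie in [0, 100]", s))
  }
  siRef <- annualStressIndex(object@cs, object@ds, object@hs, object@ws)
  if (abs(object@si - siRef) > 1e-9) {
    msg <- c(msg, "si is not the stress product of cs, ds, hs, ws")
  }
  if (length(object@limitingFlags) > 0 && object@ei != 0) {
    msg <- c(msg, "ei must be 0 whenever a limiting flag is set")
  }
  bad <- setdiff(object@limitingFlags,
                 c("GEN_LT_1", "CS_GE_100", "TI_ZERO", "MI_ZERO"))
  if (length(bad)) msg <- c(msg, paste("unknown limiting flag:", bad[1L]))
  if (length(msg) == 0L) TRUE else msg
})

#' Gridded suitability product
#'
#' Per-cell Ecoclimatic Index, favourability class, limiting flags and
#' cell areas for one scenario run.
#'
#' @slot spec [GridSpec] geometry.
#' @slot ei numeric. Per-cell EI, 0-100 (NA outside the mask).
#' @slot eiClass factor. Favourability class per cell, levels
#'   \code{unfavourable < marginal < favourable < highly_favourable}.
#' @slot flags matrix. Logical \code{nCells x 4} limiting-condition mask,
#'   columns \code{GEN_LT_1}, \code{CS_GE_100}, \code{TI_ZERO}, \code{MI_ZERO}.
#' @slot cellArea numeric. Per-cell area (km^2).
#' @slot mask logical. Study-region mask.
#' @slot results data.frame. Per-cell annual indices (giA, cs, hs, ds,
#'   ws, si, ddAnnual, generations, ei).
#' @export
setClass("SuitabilityGrid",
  representation(
    spec = "GridSpec", ei = "numeric", eiClass = "factor",
    flags = "matrix", cellArea = "numeric", mask = "logical",
    results = "data.frame"
  )
)

setValidity("SuitabilityGrid", function(object) {
  msg <- character()
  n <- nCells(object@spec)
  if (length(object@ei) != n) msg <- c(msg, "ei must have one value per cell")
  if (length(object@eiClass) != n) msg <- c(msg, "eiClass must have one value per cell")
  if (!identical(levels(object@eiClass), eiClassLevels())) {
    msg <- c(msg, "class levels must be the four favourability classes")
  }
  if (nrow(object@flags) != n || ncol(object@flags) != 4L) {
    msg <- c(msg, "flags must be an nCells x 4 logical matrix")
  }
  if (length(object@cellArea) != n || any(object@cellArea <= 0)) {
    msg <- c(msg, "cellArea must be positive for every cell")
  }
  ok <- which(object@mask & !is.na(object@ei))
  if (length(ok)) {
    if (any(object@ei[ok] < 0 | object@ei[ok] > 100)) {
      msg <- c(msg, "ei must lie in [0, 100]")
    }
    expect <- classifyEi(object@ei[ok])
    if (!identical(as.character(expect), as.character(object@eiClass[ok]))) {
      msg <- c(msg, "class is inconsistent with ei under the classification rule")
    }
  }
  if (length(msg) == 0L) TRUE else msg
})
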