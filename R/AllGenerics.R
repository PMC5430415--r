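#' Grid geometry accessors
#'
#' @param x an object carrying a [GridSpec] (a `GridSpec`, `ClimateGrid`
#'   or `SuitabilityGrid`).
#' @return `gridSpec` returns the [GridSpec]; `nCells` the number of
#'   cells; `cellCenters` a data.frame with columns `cell`, `lon`, `lat`;
#'   `cellAreas` the per-cell area in km^2.
#' @name grid-accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname grid-accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname grid-accessors
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname grid-accessors
#' @export
setGeneric("cellAreas", function(x) standardGeneric("cellAreas"))

#' Suitability accessors
#'
#' @param x a [SuitabilityGrid].
#' @return `eiValues` returns the per-cell Ecoclimatic Index (numeric,
#'   NA outside the mask); `eiClass` the per-cell favourability class
#'   (ordered factor); `limitingFlags` the logical `nCells x 4` matrix of
#'   limiting conditions; `gridMask` the study-region mask.
#' @name suitability-accessors
#' @export
setGeneric("eiValues", function(x) standardGeneric("eiValues"))

#' @rdname suitability-accessors
#' @export
setGeneric("eiClass", function(x) standardGeneric("eiClass"))

#' @rdname suitability-accessors
#' @export
setGeneric("limitingFlags", function(x) standardGeneric("limitingFlags"))

#' @rdname suitability-accessors
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))

setMethod("gridSpec", "GridSpec", function(x) x)
setMethod("gridSpec", "ClimateGrid", function(x) x@spec)
setMethod("gridSpec", "SuitabilityGrid", function(x) x@spec)

setMethod("nCells", "GridSpec", function(x) as.integer(x@nCols * x@nRows))
setMethod("nCells", "ClimateGrid", function(x) nCells(x@spec))
setMethod("nCells", "SuitabilityGrid", function(x) nCells(x@spec))

setMethod("cellCenters", "GridSpec", function(x) {
  col <- rep(seq_len(x@nCols), times = x@nRows)
  row <- rep(seq_len(x@nRows), each = x@nCols)
  data.frame(
    cell = seq_len(nCells(x)),
    lon = x@lonOrigin + (col - 0.5) * x@cellSize,
    lat = x@latOrigin + (row - 0.5) * x@cellSize
  )
})
setMethod("cellCenters", "ClimateGrid", function(x) cellCenters(x@spec))
setMethod("cellCenters", "SuitabilityGrid", function(x) cellCenters(x@spec))

setMethod("cellAreas", "GridSpec", function(x) {
  lat <- cellCenters(x)$lat
  (111.32 * x@cellSize)^2 * cos(lat * pi / 180)
})
setMethod("cellAreas", "ClimateGrid", function(x) cellAreas(x@spec))
setMethod("cellAreas", "SuitabilityGrid", function(x) x@cellArea)

setMethod("eiValues", "SuitabilityGrid", function(x) x@ei)
setMethod("eiClass", "SuitabilityGrid", function(x) x@eiClass)
setMethod("limitingFlags", "SuitabilityGrid", function(x) x@flags)
setMethod("gridMask", "SuitabilityGrid", function(x) x@mask)
setMethod("gridMask", "ClimateGrid", function(x) x@mask)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d cols x %d rows, %.4g deg cells, SW corner (%.4g, %.4g)\n",
    object@nCols, object@nRows, object@cellSize,
    object@lonOrigin, object@latOrigin
  ))
})

setMethod("show", "SpeciesParams", function(object) {
  cat("SpeciesParams\n")
  cat(sprintf("  temperature (degC): DV0=%g DV1=%g DV2=%g DV3=%g\n",
              object@dv0, object@dv1, object@dv2, object@dv3))
  cat(sprintf("  soil moisture:      SM0=%g SM1=%g SM2=%g SM3=%g\n",
              object@sm0, object@sm1, object@sm2, object@sm3))
  cat(sprintf("  cold stress: TTCS=%g THCS=%g   heat stress: TTHS=%g THHS=%g\n",
              object@ttcs, object@thcs, object@tths, object@thhs))
  cat(sprintf("  dry stress:  SMDS=%g HDS=%g   wet stress:  SMWS=%g HWS=%g\n",
              object@smds, object@hds, object@smws, object@hws))
  if (object@pddEnabled) {
    cat(sprintf("  PDD: %g degree-days per generation\n", object@pdd))
  } else {
    cat("  PDD: generation constraint disabled\n")
  }
})

setMethod("show", "MonthlyClimate", function(object) {
  cat("MonthlyClimate (12 months)\n")
  cat(sprintf("  tavg %.1f..%.1f degC, annual precip %.0f mm, RH %.0f-%.0f%%\n",
              min((object@tmax + object@tmin) / 2),
              max((object@tmax + object@tmin) / 2),
              sum(object@prcp),
              min(pmin(object@rh09, object@rh15)),
              max(pmax(object@rh09, object@rh15))))
})

setMethod("show", "ClimateGrid", function(object) {
  show(object@spec)
  cat(sprintf("ClimateGrid: %d cells (%d masked out), elevation %.0f-%.0f m\n",
              nCells(object), sum(!object@mask),
              min(object@elevation), max(object@elevation)))
})

setMethod("show", "CellResult", function(object) {
  cat(sprintf("CellResult: EI = %.2f (GI_A %.2f, SI %.4f)\n",
              object@ei, object@giA, object@si))
  cat(sprintf("  stresses CS %.1f HS %.1f DS %.1f WS %.1f; DD %.0f -> %.2f generations\n",
              object@cs, object@hs, object@ds, object@ws,
              object@ddAnnual,
              if (is.na(object@generations)) NA_real_ else object@generations))
  if (length(object@limitingFlags)) {
    cat("  limiting:", paste(object@limitingFlags, collapse = ", "), "\n")
  }
})

setMethod("show", "SuitabilityGrid", function(object) {
  show(object@spec)
  ok <- object@mask
  cat(sprintf("SuitabilityGrid: mean EI %.2f over %d cells\n",
              mean(object@ei[ok]), sum(ok)))
  print(table(object@eiClass[ok]))
})
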