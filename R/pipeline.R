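# Pipeline orchestration: reproducible scenario runs, scenario
# comparison, occurrence validation and sensitivity sweeps, each writing
# CSV products with a metadata header (tool version, config hash, seed).
# A thin command-line wrapper over these functions ships in
# inst/cli/ecoclimex.R.

#' Build a run configuration
#'
#' A validated list driving the pipeline commands.  The climate source
#' is either the built-in synthetic generator (default; `seed` and
#' `spec` define it) or a pair of long-format climate-grid CSV files.
#'
#' @param outDir output directory (created if absent).
#' @param spec [GridSpec-class] of the study grid (used by the synthetic
#'   source).
#' @param seed integer seed for the synthetic climate source.
#' @param params a [SpeciesParams-class] object, or `paramsFile` to read
#'   one from a flat key-value file.
#' @param paramsFile optional parameter file overriding `params`.
#' @param climateCsv,futureClimateCsv optional current/future climate
#'   grids (long-format CSV, see [writeClimateGridCsv()]); when absent
#'   the synthetic current/future pair for `(spec, seed)` is used.
#' @param capacity soil bucket capacity (mm).
#' @param evapK evaporative demand coefficient.
#' @param regions optional named list of cell-index vectors (region
#'   mask) for impact-index summaries; default five latitude bands.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(outDir,
                      spec = GridSpec(98, 18, 0.5, 50, 50),
                      seed = 1L,
                      params = defaultFornicatusParams(),
                      paramsFile = NULL,
                      climateCsv = NULL,
                      futureClimateCsv = NULL,
                      capacity = 100,
                      evapK = 0.8,
                      regions = NULL) {
  if (!is.null(paramsFile)) {
    if (!file.exists(paramsFile)) stop("paramsFile not found: ", paramsFile)
    params <- readParamsFile(paramsFile)
  }
  v <- validateParams(params)
  if (length(v)) stop("invalid parameter set: ", paste(v, collapse = "; "))
  for (f in c(climateCsv, futureClimateCsv)) {
    if (!file.exists(f)) stop("climate file not found: ", f)
  }
  cfg <- list(outDir = outDir, spec = spec, seed = as.integer(seed),
              params = params, climateCsv = climateCsv,
              futureClimateCsv = futureClimateCsv,
              capacity = capacity, evapK = evapK,
              regions = if (is.null(regions)) latBandRegions(spec) else regions)
  class(cfg) <- "RunConfig"
  cfg
}

configClimate <- function(cfg, scenario = c("current", "future")) {
  scenario <- match.arg(scenario)
  path <- if (scenario == "current") cfg$climateCsv else cfg$futureClimateCsv
  if (!is.null(path)) {
    readClimateGridCsv(path)
  } else {
    generateSyntheticRegion(cfg$spec, cfg$seed, scenario)
  }
}

configHash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(cfg[setdiff(names(cfg), "outDir")]), tf)
  unname(tools::md5sum(tf))
}

metadataHeader <- function(cfg) {
  c(sprintf("# tool: ecoclimex %s",
            as.character(utils::packageVersion("ecoclimex"))),
    sprintf("# config_hash: %s", configHash(cfg)),
    sprintf("# seed: %d", cfg$seed))
}

writeProduct <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metadataHeader(cfg), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a pipeline CSV product
#'
#' Reads a CSV written by the pipeline commands, skipping the
#' `#`-prefixed metadata header (returned as an attribute).
#'
#' @param path CSV file path.
#' @return data.frame with attribute `metadata`.
#' @export
readProduct <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  df
}

suitabilityTable <- function(sg) {
  cc <- cellCenters(sg@spec)
  f <- limitingFlags(sg)
  flagStr <- apply(f, 1L, function(r) {
    paste(colnames(f)[r], collapse = "|")
  })
  data.frame(cell = cc$cell, lon = cc$lon, lat = cc$lat,
             ei = sg@ei, class = as.character(sg@eiClass),
             flags = flagStr, area_km2 = sg@cellArea,
             masked = !sg@mask)
}

#' Run one scenario end to end
#'
#' Computes the suitability grid for one scenario and writes the
#' per-cell EI/class/flags table (`ei_<scenario>.csv`), the per-class
#' area summary (`areas_<scenario>.csv`) and the per-region impact
#' indices of the four limiting conditions
#' (`impact_<scenario>.csv`).
#'
#' @param cfg a [runConfig()] object.
#' @param scenario `"current"` or `"future"`.
#' @return the [SuitabilityGrid-class], invisibly; file paths in
#'   attribute `files`.
#' @export
runScenario <- function(cfg, scenario = c("current", "future")) {
  stopifnot(inherits(cfg, "RunConfig"))
  scenario <- match.arg(scenario)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  grid <- configClimate(cfg, scenario)
  message(sprintf("runScenario[%s]: %d cells, seed %d",
                  scenario, nCells(grid), cfg$seed))
  sg <- runGrid(grid, cfg$params, capacity = cfg$capacity, evapK = cfg$evapK)

  files <- file.path(cfg$outDir, sprintf(
    c("ei_%s.csv", "areas_%s.csv", "impact_%s.csv"), scenario))
  writeProduct(suitabilityTable(sg), files[1L], cfg)
  writeProduct(areaSummary(sg), files[2L], cfg)

  masks <- limitingFactorMap(sg)
  impact <- do.call(rbind, lapply(names(cfg$regions), function(rn) {
    data.frame(region = rn, condition = names(masks),
               impact = vapply(masks, impactIndex, integer(1),
                               region = cfg$regions[[rn]], spec = sg@spec),
               row.names = NULL)
  }))
  writeProduct(impact, files[3L], cfg)
  attr(sg, "files") <- files
  invisible(sg)
}

#' Compare the current and future scenarios
#'
#' Runs both scenarios of the configured pair and writes the per-cell
#' EI change (`ei_change.csv`), the per-class area change table
#' (`area_change.csv`), per-class range shifts (`range_shift.csv`) and
#' the class-transition matrix (`transitions.csv`, cell counts moving
#' between classes).
#'
#' @param cfg a [runConfig()] object.
#' @return list with `current`, `future` ([SuitabilityGrid-class]),
#'   `difference` (see [eiDifference()]), `areaChange`, `rangeShift`
#'   and `transitions`.
#' @export
compareScenarios <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  cur <- runScenario(cfg, "current")
  fut <- runScenario(cfg, "future")
  diffr <- eiDifference(cur, fut)

  cc <- cellCenters(cfg$spec)
  writeProduct(
    data.frame(cell = cc$cell, lon = cc$lon, lat = cc$lat,
               delta_ei = diffr$delta),
    file.path(cfg$outDir, "ei_change.csv"), cfg)

  ac <- merge(areaSummary(cur), areaSummary(fut), by = "class",
              suffixes = c("_current", "_future"), sort = FALSE)
  ac$area_change_km2 <- ac$area_km2_future - ac$area_km2_current
  writeProduct(ac, file.path(cfg$outDir, "area_change.csv"), cfg)

  shifts <- data.frame(
    class = eiClassLevels(),
    shift_deg = vapply(eiClassLevels(), function(cl) {
      suppressWarnings(rangeShift(cur, fut, cl))
    }, numeric(1))
  )
  writeProduct(shifts, file.path(cfg$outDir, "range_shift.csv"), cfg)

  ok <- gridMask(cur) & gridMask(fut)
  trans <- table(current = cur@eiClass[ok], future = fut@eiClass[ok])
  writeProduct(as.data.frame(trans),
               file.path(cfg$outDir, "transitions.csv"), cfg)

  list(current = cur, future = fut, difference = diffr,
       areaChange = ac, rangeShift = shifts, transitions = trans)
}

#' Validate occurrence records against a configured run
#'
#' Runs the current scenario and scores the validation occurrence
#' records against its suitability classes; writes `validation.csv`
#' (per-point classes plus a summary row is logged).
#'
#' @param cfg a [runConfig()] object.
#' @param occurrences occurrence data.frame (see [readOccurrenceCsv()])
#'   or a path to an occurrence CSV.  Rows with a `role` column are
#'   filtered to `role == "validation"`.
#' @return the [validateOccurrences()] result list.
#' @export
validateRun <- function(cfg, occurrences) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (is.character(occurrences)) occurrences <- readOccurrenceCsv(occurrences)
  if ("role" %in% names(occurrences)) {
    occurrences <- occurrences[occurrences$role == "validation", , drop = FALSE]
  }
  if (nrow(occurrences) == 0L) stop("no validation occurrence records")
  sg <- runScenario(cfg, "current")
  res <- validateOccurrences(occurrences, sg)
  writeProduct(res$table, file.path(cfg$outDir, "validation.csv"), cfg)
  message(sprintf("validation: %.1f%% of %d usable record(s) in suitable habitat",
                  res$percentSuitable, res$nUsed))
  res
}

#' Run the configured sensitivity sweep
#'
#' @param cfg a [runConfig()] object.
#' @param plan per-parameter candidate values; default
#'   [defaultSensitivityPlan()] for the configured parameter set.
#' @return the [sweepAll()] record table (also written to
#'   `sensitivity.csv`).
#' @export
runSensitivity <- function(cfg, plan = defaultSensitivityPlan(cfg$params)) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  grid <- configClimate(cfg, "current")
  tab <- sweepAll(cfg$params, grid, plan,
                  capacity = cfg$capacity, evapK = cfg$evapK)
  writeProduct(tab, file.path(cfg$outDir, "sensitivity.csv"), cfg)
  tab
}

#' Materialize the synthetic scenario pair as CSV files
#'
#' @param cfg a [runConfig()] object.
#' @return paths of the two written climate-grid CSV files.
#' @export
makeSyntheticScenario <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(cfg$outDir, c("climate_current.csv", "climate_future.csv"))
  writeClimateGridCsv(generateSyntheticRegion(cfg$spec, cfg$seed, "current"),
                      paths[1L])
  writeClimateGridCsv(generateSyntheticRegion(cfg$spec, cfg$seed, "future"),
                      paths[2L])
  paths
}
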