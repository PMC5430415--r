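sensitivityParameters <- function() {
  c("DV0", "DV1", "DV2", "DV3", "TTCS", "PDD", "SM0", "SM1", "SM2", "SM3")
}

#' Mean Ecoclimatic Index over a climate grid
#'
#' The average EI over all unmasked cells, zeros included.
#'
#' @param grid a [ClimateGrid-class] object.
#' @param p a [SpeciesParams-class] object.
#' @param capacity,evapK engine settings, see [runGrid()].
#' @return mean EI (0-100).
#' @export
meanEi <- function(grid, p, capacity = 100, evapK = 0.8) {
  res <- runCellsMatrix(grid, p, capacity = capacity, evapK = evapK)
  mean(res$ei)
}

#' One-at-a-time parameter sensitivity
#'
#' Rebuilds the parameter set with a single field replaced by each
#' candidate value, reruns the full engine over the grid, and records
#' the mean EI and its change from the baseline (fitted) parameter set.
#' Candidate values that would violate the parameter invariants (e.g. a
#' DV0 above DV1) are skipped with a message.
#'
#' @param base baseline [SpeciesParams-class].
#' @param climate a [ClimateGrid-class] object.
#' @param parameter one of `DV0`-`DV3`, `TTCS`, `PDD`, `SM0`-`SM3`
#'   (case-insensitive).
#' @param values numeric candidate values in the parameter's units.
#' @param capacity,evapK engine settings.
#' @return data.frame with columns `parameter`, `perturbed_value`,
#'   `mean_ei`, `delta_mean_ei` (0 at the fitted value).
#' @export
oneAtATime <- function(base, climate, parameter, values,
                       capacity = 100, evapK = 0.8) {
  parameter <- toupper(parameter)
  if (!parameter %in% sensitivityParameters()) {
    stop("unknown sensitivity parameter: ", parameter,
         " (expected one of ", paste(sensitivityParameters(), collapse = ", "), ")")
  }
  field <- tolower(parameter)
  baseMean <- meanEi(climate, base, capacity = capacity, evapK = evapK)
  rows <- lapply(values, function(val) {
    p <- tryCatch(
      do.call(updateParams, c(list(base), stats::setNames(list(val), field))),
      error = function(e) NULL
    )
    if (is.null(p)) {
      message(sprintf("skipping %s = %g: violates parameter invariants",
                      parameter, val))
      return(NULL)
    }
    m <- if (identical(val, slot(base, field))) {
      baseMean
    } else {
      meanEi(climate, p, capacity = capacity, evapK = evapK)
    }
    data.frame(parameter = parameter, perturbed_value = val,
               mean_ei = m, delta_mean_ei = m - baseMean)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(parameter = character(), perturbed_value = numeric(),
                      mean_ei = numeric(), delta_mean_ei = numeric())
  }
  out
}

#' Default one-at-a-time sweep plan
#'
#' Each parameter is perturbed by -10%, -5%, 0, +5% and +10% of its
#' fitted value (PDD included, on its own much larger axis).
#'
#' @param base baseline [SpeciesParams-class].
#' @param fractions relative perturbations.
#' @param parameters subset of the sweep parameters.
#' @return named list of candidate value vectors, one per parameter.
#' @export
defaultSensitivityPlan <- function(base = defaultFornicatusParams(),
                                   fractions = c(-0.1, -0.05, 0, 0.05, 0.1),
                                   parameters = sensitivityParameters()) {
  parameters <- toupper(parameters)
  bad <- setdiff(parameters, sensitivityParameters())
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  plan <- lapply(parameters, function(pn) {
    slot(base, tolower(pn)) * (1 + fractions)
  })
  stats::setNames(plan, parameters)
}

#' Run a full sensitivity sweep
#'
#' Batch driver over a per-parameter plan; records are ordered by
#' parameter (plan order) then by candidate value order.
#'
#' @param base baseline [SpeciesParams-class].
#' @param climate a [ClimateGrid-class] object.
#' @param plan named list of candidate value vectors (names are the
#'   sweep parameter mnemonics); see [defaultSensitivityPlan()].
#' @param capacity,evapK engine settings.
#' @return data.frame of concatenated [oneAtATime()] records.
#' @export
sweepAll <- function(base, climate, plan = defaultSensitivityPlan(base),
                     capacity = 100, evapK = 0.8) {
  if (length(plan) == 0L || is.null(names(plan))) {
    stop("plan must be a non-empty named list of value vectors")
  }
  do.call(rbind, lapply(names(plan), function(pn) {
    oneAtATime(base, climate, pn, plan[[pn]],
               capacity = capacity, evapK = evapK)
  }))
}
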