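#' Construct a species parameter set
#'
#' Low-level constructor; most users start from
#' [defaultFornicatusParams()] or [wetTropicalTemplate()] and modify
#' fields with [updateParams()].
#'
#' @param dv0,dv1,dv2,dv3 temperature response thresholds (degrees C).
#' @param sm0,sm1,sm2,sm3 soil-moisture response thresholds (fraction of
#'   bucket capacity).
#' @param ttcs,thcs cold stress threshold (degrees C) and signed rate (per week).
#' @param tths,thhs heat stress threshold (degrees C) and rate (per week).
#' @param smds,hds dry stress threshold (fraction) and signed rate (per week).
#' @param smws,hws wet stress threshold (fraction) and rate (per week).
#' @param pdd degree-days above `dv0` required for one generation.
#' @param pddEnabled whether the generation constraint is applied.
#' @return a validated [SpeciesParams-class] object.
#' @export
SpeciesParams <- function(dv0, dv1, dv2, dv3, sm0, sm1, sm2, sm3,
                          ttcs, thcs, tths, thhs, smds, hds, smws, hws,
                          pdd, pddEnabled = TRUE) {
  new("SpeciesParams",
      dv0 = dv0, dv1 = dv1, dv2 = dv2, dv3 = dv3,
      sm0 = sm0, sm1 = sm1, sm2 = sm2, sm3 = sm3,
      ttcs = ttcs, thcs = thcs, tths = tths, thhs = thhs,
      smds = smds, hds = hds, smws = smws, hws = hws,
      pdd = pdd, pddEnabled = pddEnabled)
}

#' Fitted parameter set for Euwallacea fornicatus
#'
#' The final fitted parameter values for the polyphagous shot-hole
#' borer: lower development threshold 15 degrees C (immature stages do
#' not survive below it), optimum range 26-35 degrees C, upper limit 40
#' degrees C; soil-moisture response 0.05/0.3/1/2.5; cold stress below
#' -10 degrees C at 0.005 per week, heat stress above 42 degrees C at
#' 0.0002 per week, dry stress below soil moisture 0.05 at 0.001 per
#' week, wet stress above 2.5 at 0.005 per week; 373 degree-days above
#' the threshold per generation (sum of ~237 DD egg-to-adult and ~136 DD
#' preoviposition).
#'
#' @return a [SpeciesParams-class] object.
#' @examples
#' p <- defaultFornicatusParams()
#' temperatureIndex(30, p)   # 1: inside the optimum plateau
#' @export
defaultFornicatusParams <- function() {
  SpeciesParams(
    dv0 = 15, dv1 = 26, dv2 = 35, dv3 = 40,
    sm0 = 0.05, sm1 = 0.3, sm2 = 1, sm3 = 2.5,
    ttcs = -10, thcs = -0.005,
    tths = 42, thhs = 0.0002,
    smds = 0.05, hds = -0.001,
    smws = 2.5, hws = 0.005,
    pdd = 373, pddEnabled = TRUE
  )
}

#' Wet tropical template parameter set
#'
#' The generic wet-tropical starting template from which the fitted
#' parameter set was derived.  The template's dry stress rate is stored
#' sign-normalized (negative); its PDD of 0 means "no generation
#' constraint" and is represented by `pddEnabled = FALSE` rather than a
#' zero divisor.
#'
#' @return a [SpeciesParams-class] object.
#' @export
wetTropicalTemplate <- function() {
  SpeciesParams(
    dv0 = 15, dv1 = 28, dv2 = 33, dv3 = 36,
    sm0 = 0.35, sm1 = 0.7, sm2 = 1.5, sm3 = 2.5,
    ttcs = 2, thcs = 0,
    tths = 37, thhs = 0.0002,
    smds = 0.25, hds = -0.01,
    smws = 2.5, hws = 0.002,
    pdd = 0, pddEnabled = FALSE
  )
}

#' Check a parameter set against its invariants
#'
#' Returns a character vector of violation descriptions, empty when the
#' parameter set is internally consistent.  Checked: the orderings
#' `dv0 < dv1 <= dv2 < dv3` and `sm0 < sm1 <= sm2 <= sm3`, the stress
#' rate sign conventions (`thcs <= 0`, `hds <= 0`, `thhs >= 0`,
#' `hws >= 0`), `pdd > 0` when the generation constraint is enabled, and
#' finiteness of every field.
#'
#' @param p a [SpeciesParams-class] object.
#' @return character vector of violations (empty when valid).
#' @export
validateParams <- function(p) {
  msg <- character()
  fields <- paramFieldNames()
  for (f in fields) {
    x <- slot(p, f)
    if (length(x) != 1L || !is.finite(x)) {
      msg <- c(msg, sprintf("%s must be a single finite number", f))
    }
  }
  if (length(p@pddEnabled) != 1L || is.na(p@pddEnabled)) {
    msg <- c(msg, "pddEnabled must be TRUE or FALSE")
  }
  if (length(msg)) return(msg)
  if (!(p@dv0 < p@dv1)) msg <- c(msg, "dv0 < dv1 violated")
  if (!(p@dv1 <= p@dv2)) msg <- c(msg, "dv1 <= dv2 violated")
  if (!(p@dv2 < p@dv3)) msg <- c(msg, "dv2 < dv3 violated")
  if (!(p@sm0 < p@sm1)) msg <- c(msg, "sm0 < sm1 violated")
  if (!(p@sm1 <= p@sm2)) msg <- c(msg, "sm1 <= sm2 violated")
  if (!(p@sm2 <= p@sm3)) msg <- c(msg, "sm2 <= sm3 violated")
  if (p@pddEnabled && !(p@pdd > 0)) {
    msg <- c(msg, "pdd > 0 violated (generation check enabled)")
  }
  if (p@thcs > 0) msg <- c(msg, "thcs <= 0 violated")
  if (p@hds > 0) msg <- c(msg, "hds <= 0 violated")
  if (p@thhs < 0) msg <- c(msg, "thhs >= 0 violated")
  if (p@hws < 0) msg <- c(msg, "hws >= 0 violated")
  msg
}

paramFieldNames <- function() {
  c("dv0", "dv1", "dv2", "dv3", "sm0", "sm1", "sm2", "sm3",
    "ttcs", "thcs", "tths", "thhs", "smds", "hds", "smws", "hws", "pdd")
}

paramFileKeys <- function() toupper(paramFieldNames())

#' Replace single fields of a parameter set
#'
#' @param p a [SpeciesParams-class] object.
#' @param ... named replacements using the lower-case field names
#'   (`dv0` ... `pdd`, `pddEnabled`).
#' @param validate reject the result if it violates the invariants.
#' @return the modified [SpeciesParams-class] object.
#' @examples
#' updateParams(defaultFornicatusParams(), dv0 = 14)
#' @export
updateParams <- function(p, ..., validate = TRUE) {
  repl <- list(...)
  known <- c(paramFieldNames(), "pddEnabled")
  bad <- setdiff(names(repl), known)
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  for (f in names(repl)) slot(p, f) <- repl[[f]]
  if (validate) {
    v <- validateParams(p)
    if (length(v)) stop("invalid parameter set: ", paste(v, collapse = "; "))
  }
  p
}

#' Read / write a flat key-value parameter file
#'
#' The file holds one `KEY = value` pair per line using the upper-case
#' parameter mnemonics (`DV0`, ..., `PDD`); `#` starts a comment.  A
#' `PDD` of 0 round-trips to the disabled generation constraint.  Values
#' are written with full precision so a write/read cycle is lossless.
#'
#' @param path file path.
#' @param p a [SpeciesParams-class] object (for `writeParamsFile`).
#' @return `readParamsFile` returns a [SpeciesParams-class] object;
#'   `writeParamsFile` returns `path` invisibly.
#' @export
readParamsFile <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) {
    stop("malformed parameter line: ", lines[which(lengths(kv) != 2L)[1L]])
  }
  keys <- toupper(trimws(vapply(kv, `[[`, "", 1L)))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals)) stop("non-numeric value for key ", keys[which(is.na(vals))[1L]])
  missing <- setdiff(paramFileKeys(), keys)
  if (length(missing)) stop("missing parameter key(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicated parameter key: ", keys[duplicated(keys)][1L])
  val <- stats::setNames(vals, keys)
  args <- as.list(val[paramFileKeys()])
  names(args) <- paramFieldNames()
  args$pddEnabled <- args$pdd > 0
  do.call(SpeciesParams, args)
}

#' @rdname readParamsFile
#' @export
writeParamsFile <- function(p, path) {
  vals <- vapply(paramFieldNames(), function(f) slot(p, f), numeric(1))
  if (!p@pddEnabled) vals[["pdd"]] <- 0
  writeLines(
    sprintf("%s = %s", paramFileKeys(), formatC(vals, digits = 17, format = "g")),
    path
  )
  invisible(path)
}
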