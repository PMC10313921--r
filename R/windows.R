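## Therapeutic-window parameters: each compares tumor kill against
## normal-tissue (slice) toxicity on the [-1, +1] scale, +1 = kill without
## toxicity, -1 = toxicity without kill.

.clamp1 <- function(x) pmin(pmax(x, -1), 1)

.checkPaired <- function(kill, tox) {
  if (kill@unit != tox@unit)
    stop("dose unit mismatch between tumor and toxicity curves",
         call. = FALSE)
  invisible(TRUE)
}

#' ECx therapeutic window (parameters 2-6)
#'
#' Compares slice toxicity and tumor kill at the dose where the tumor kill
#' passes through the x\% level. When the ECx is reached at dose d*, the
#' window is \code{clamp(k(d*) - tox(d*))} (at a true crossing
#' \code{k(d*) = x/100} exactly; when the crossing precedes the lowest
#' tested dose the observed kill and toxicity at that lowest dose are
#' used). When the ECx is not reached, a shortfall-penalized fallback is
#' evaluated at the top dose, \code{clamp(k_max - x/100 - tox(d_max))}, so
#' an agent that never attains the level cannot outscore one that attains
#' it at low toxicity. Toxicity at intermediate doses comes from in-range
#' interpolation on the toxicity curve's axis.
#'
#' @param kill a \code{"tumor_kill"} [DoseResponseCurve-class].
#' @param tox a \code{"slice_toxicity"} [DoseResponseCurve-class] in the
#'   same dose unit.
#' @param x target percent (10, 25, 50, 75, 90).
#' @return window value in [-1, +1].
#' @export
ecxWindow <- function(kill, tox, x) {
  .checkPaired(kill, tox)
  res <- computeEcx(kill, x)
  if (res@reached) {
    kAt <- if (res@belowRange) kill@values[1L] else x / 100
    return(.clamp1(kAt - interpolateResponse(tox, res@dose)))
  }
  dmax <- max(kill@doses)
  .clamp1(max(kill@values) - x / 100 - interpolateResponse(tox, dmax))
}

#' Max-kill therapeutic window (parameter 1)
#'
#' Kill minus toxicity at the highest tested dose:
#' \code{clamp(k(d_max) - tox(d_max))}.
#'
#' @inheritParams ecxWindow
#' @return window value in [-1, +1].
#' @export
maxKillWindow <- function(kill, tox) {
  .checkPaired(kill, tox)
  dmax <- max(kill@doses)
  .clamp1(kill@values[length(kill@values)] - interpolateResponse(tox, dmax))
}

#' Slope therapeutic window (parameter 7)
#'
#' Compares the slopes through the tumor EC50 and the slice-toxicity EC50
#' as a bounded ratio \code{(m_T - m_O) / (|m_T| + |m_O|)}, which lives on
#' the same [-1, +1] scale as the other windows. When both slopes are 0
#' the ratio is undefined and EC50 attainment breaks the tie: +1 when only
#' the tumor reaches its EC50, -1 when only the toxicity curve does, 0
#' otherwise (no steepness information either way).
#'
#' @inheritParams ecxWindow
#' @return window value in [-1, +1].
#' @export
slopeWindow <- function(kill, tox) {
  .checkPaired(kill, tox)
  mT <- computeSlopeAtEc50(kill)
  mO <- computeSlopeAtEc50(tox)
  denom <- abs(mT) + abs(mO)
  if (denom > 0) return((mT - mO) / denom)
  tReached <- !is.null(.firstCrossing(.axisCoords(kill), kill@values, 0.5))
  oReached <- !is.null(.firstCrossing(.axisCoords(tox), tox@values, 0.5))
  if (tReached && !oReached) return(1)
  if (!tReached && oReached) return(-1)
  0
}

#' AUC therapeutic window (parameter 8)
#'
#' Difference of the normalized areas under the tumor-kill and toxicity
#' curves, clamped to [-1, +1]. This is the heaviest-weighted parameter
#' (35\% of the score).
#'
#' @inheritParams ecxWindow
#' @return window value in [-1, +1].
#' @export
aucWindow <- function(kill, tox) {
  .checkPaired(kill, tox)
  .clamp1(computeNormalizedAuc(kill) - computeNormalizedAuc(tox))
}

#' Growth-acceleration window (parameter 9)
#'
#' Penalizes treated tumors that grow faster than untreated: +1 for max
#' growth up to 125\% of untreated, 0 for (125, 150]\%, -1 above 150\%.
#'
#' @param shape a [CurveShape-class] from [detectShape()].
#' @return -1, 0 or +1.
#' @export
growthWindow <- function(shape) {
  stopifnot(is(shape, "CurveShape"))
  g <- shape@maxGrowthPercent
  if (g <= 125) 1 else if (g <= 150) 0 else -1
}

#' Biphasic-killing window (parameter 10)
#'
#' -1 for a biphasic curve (rapid killing at low doses with limited
#' additional killing at higher doses), +1 otherwise.
#'
#' @param shape a [CurveShape-class] from [detectShape()].
#' @return -1 or +1.
#' @export
biphasicWindow <- function(shape) {
  stopifnot(is(shape, "CurveShape"))
  if (shape@biphasic) -1 else 1
}

#' Incomplete-kill window (parameter 11)
#'
#' Scores residual tumor at the highest dose: +1 for < 10\% remaining, 0
#' for 10-25\%, -1 for > 25\%.
#'
#' @param shape a [CurveShape-class] from [detectShape()].
#' @return -1, 0 or +1.
#' @export
incompleteKillWindow <- function(shape) {
  stopifnot(is(shape, "CurveShape"))
  r <- shape@remainingAtMax
  if (r < 10) 1 else if (r <= 25) 0 else -1
}

#' Compute all eleven therapeutic windows for one interaction
#'
#' Runs the full window panel on a paired tumor survival curve and slice
#' toxicity curve: max kill, EC10/25/50/75/90, slope, AUC (tumor vs
#' toxicity comparisons) and growth/biphasic/incomplete (tumor-curve
#' behavior). Per-ECx not-reached flags are recorded so reports can mark
#' windows that used the shortfall fallback.
#'
#' @param tumor a \code{"tumor_survival"} [DoseResponseCurve-class].
#' @param tox a \code{"slice_toxicity"} [DoseResponseCurve-class] in the
#'   same dose unit.
#' @param tumorId,drugId identifiers carried into results.
#' @param lowKillMin,tailGainMax,remainingMin biphasic-rule thresholds,
#'   see [detectShape()].
#' @return a [TherapeuticWindows-class].
#' @examples
#' s <- DoseResponseCurve(10^(0:5), c(1, .9, .6, .3, .1, .05), "tumor_survival")
#' tx <- DoseResponseCurve(10^(0:5), c(0, 0, .05, .1, .2, .3), "slice_toxicity")
#' computeAllWindows(s, tx)
#' @export
computeAllWindows <- function(tumor, tox, tumorId = NA_character_,
                              drugId = NA_character_, lowKillMin = 0.25,
                              tailGainMax = 0.10, remainingMin = 10) {
  stopifnot(is(tumor, "DoseResponseCurve"), is(tox, "DoseResponseCurve"))
  if (tumor@kind != "tumor_survival")
    stop("tumor curve must be of kind tumor_survival", call. = FALSE)
  if (tox@kind != "slice_toxicity")
    stop("tox curve must be of kind slice_toxicity", call. = FALSE)
  .checkPaired(tumor, tox)
  kill <- killFraction(tumor)
  shape <- detectShape(tumor, lowKillMin = lowKillMin,
                       tailGainMax = tailGainMax,
                       remainingMin = remainingMin)
  ecx <- vapply(.ECX_LEVELS, function(x) ecxWindow(kill, tox, x), numeric(1))
  nr <- vapply(.ECX_LEVELS,
               function(x) !computeEcx(kill, x)@reached, logical(1))
  names(nr) <- paste0("ec", .ECX_LEVELS)
  v <- c(maxKillWindow(kill, tox), ecx, slopeWindow(kill, tox),
         aucWindow(kill, tox), growthWindow(shape), biphasicWindow(shape),
         incompleteKillWindow(shape))
  names(v) <- .WINDOW_NAMES
  new("TherapeuticWindows", values = v, nrFlags = nr,
      tumorId = as.character(tumorId), drugId = as.character(drugId))
}

#' Construct a TherapeuticWindows object directly
#'
#' For analytic work with known window values (e.g. checking weights).
#'
#' @param values numeric(11) in canonical order (may be named).
#' @param nrFlags logical(5) for ec10..ec90 (default all FALSE).
#' @param tumorId,drugId identifiers.
#' @return a [TherapeuticWindows-class].
#' @export
TherapeuticWindows <- function(values, nrFlags = NULL,
                               tumorId = NA_character_,
                               drugId = NA_character_) {
  values <- as.numeric(values)
  names(values) <- .WINDOW_NAMES
  if (is.null(nrFlags)) nrFlags <- rep(FALSE, 5L)
  names(nrFlags) <- paste0("ec", .ECX_LEVELS)
  new("TherapeuticWindows", values = values, nrFlags = nrFlags,
      tumorId = as.character(tumorId), drugId = as.character(drugId))
}

#' @rdname TherapeuticWindows
#' @param object a [TherapeuticWindows-class].
#' @export
setMethod("windowValues", "TherapeuticWindows", function(object) object@values)

#' @rdname TherapeuticWindows
#' @export
setMethod("nrFlags", "TherapeuticWindows", function(object) object@nrFlags)

setMethod("show", "TherapeuticWindows", function(object) {
  cat(sprintf("TherapeuticWindows [%s x %s]\n",
              object@drugId, object@tumorId))
  print(round(object@values, 3))
  if (any(object@nrFlags))
    cat("  NR fallback used for:",
        paste(names(object@nrFlags)[object@nrFlags], collapse = ", "), "\n")
})

#' Windows table for a list of TherapeuticWindows
#'
#' @param windowsList list of [TherapeuticWindows-class] objects.
#' @return data.frame with tumor_id, drug_id, the eleven window columns
#'   and nr_* flag columns — one row per drug-tumor pair.
#' @export
windowsTable <- function(windowsList) {
  rows <- lapply(windowsList, function(w) {
    v <- as.list(w@values)
    nr <- as.list(w@nrFlags)
    names(nr) <- paste0("nr_", names(w@nrFlags))
    data.frame(tumor_id = w@tumorId, drug_id = w@drugId, v, nr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
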