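#' Piecewise-linear interpolation of a dose-response curve
#'
#' Evaluates the curve at an arbitrary in-range dose by linear
#' interpolation between tabulated doses on the curve's interpolation axis
#' (log10 dose for concentrations by default, linear dose for Gy). Values
#' come straight from the measured points; no parametric curve is fitted.
#' Extrapolation beyond the tested dose range is refused.
#'
#' @param curve a [DoseResponseCurve-class].
#' @param dose query dose (same unit as the curve), within
#'   \code{[min(doses), max(doses)]}.
#' @return the interpolated response fraction.
#' @examples
#' k <- DoseResponseCurve(c(1, 10), c(0.2, 0.6), "tumor_kill")
#' interpolateResponse(k, 10^0.5)  # 0.4: midpoint on the log10 axis
#' @export
interpolateResponse <- function(curve, dose) {
  stopifnot(is(curve, "DoseResponseCurve"))
  d <- curve@doses
  if (any(dose < min(d) - 1e-12 * min(d)) ||
      any(dose > max(d) + 1e-12 * max(d)))
    stop(sprintf("dose outside the tested range [%g, %g]: no extrapolation",
                 min(d), max(d)), call. = FALSE)
  dose <- pmin(pmax(dose, min(d)), max(d))
  a <- .axisCoords(curve)
  q <- if (curve@axis == "log") log10(dose) else dose
  stats::approx(a, curve@values, xout = q, method = "linear",
                ties = "ordered")$y
}

## First upward crossing of `values` through `target`, scanning low to
## high on axis coordinates `a`. Returns list(coord, index, belowRange) or
## NULL when the target is never attained (max value < target).
.firstCrossing <- function(a, values, target) {
  hit <- which(values >= target)
  if (length(hit) == 0L) return(NULL)
  i <- hit[1L]
  if (i == 1L) return(list(coord = a[1L], index = 1L, belowRange = TRUE))
  frac <- (target - values[i - 1L]) / (values[i] - values[i - 1L])
  list(coord = a[i - 1L] + frac * (a[i] - a[i - 1L]), index = i,
       belowRange = FALSE)
}

.ecxFromSeries <- function(curve, x) {
  a <- .axisCoords(curve)
  cr <- .firstCrossing(a, curve@values, x / 100)
  if (is.null(cr))
    return(new("EcxResult", x = x, dose = NA_real_, reached = FALSE,
               belowRange = FALSE, unit = curve@unit))
  new("EcxResult", x = x, dose = .fromAxis(cr$coord, curve@axis),
      reached = TRUE, belowRange = cr$belowRange, unit = curve@unit)
}

#' ECx of a kill (or toxicity) series by linear interpolation
#'
#' The dose at which the response first crosses x/100, scanning from the
#' lowest tested dose upward on the interpolation axis. Non-monotone
#' curves use the first upward crossing (conservative potency estimate);
#' a curve that touches the level exactly over a flat segment reports the
#' lowest dose of that segment. When the maximal response stays below
#' x/100 the result is flagged not reached (NR); when the response already
#' meets the level at the lowest tested dose the crossing precedes the
#' grid and the lowest dose is reported with \code{belowRange = TRUE}
#' rather than extrapolating.
#'
#' @param series a [DoseResponseCurve-class] of kind \code{"tumor_kill"}
#'   or \code{"slice_toxicity"}.
#' @param x target percent, one of 10, 25, 50, 75, 90.
#' @return an [EcxResult-class].
#' @examples
#' k <- DoseResponseCurve(c(1, 10, 100), c(0.2, 0.6, 0.9), "tumor_kill")
#' computeEcx(k, 50)  # ~5.62 uM: 10^(0.75) on the log grid
#' @export
computeEcx <- function(series, x) {
  stopifnot(is(series, "DoseResponseCurve"))
  if (!series@kind %in% c("tumor_kill", "slice_toxicity"))
    stop("computeEcx() expects a tumor_kill or slice_toxicity series",
         call. = FALSE)
  if (!x %in% .ECX_LEVELS)
    stop("x must be one of 10, 25, 50, 75, 90", call. = FALSE)
  if (length(series@doses) < 2L)
    stop("ECx needs at least 2 doses", call. = FALSE)
  .ecxFromSeries(series, x)
}

#' ICx of a survival curve
#'
#' Identical machinery to [computeEcx()] applied to kill = 1 - survival;
#' IC50 is the conventional report column of screening tables, with NR
#' when the drug elicits less than 50\% death at the highest tested dose.
#'
#' @param curve a [DoseResponseCurve-class] of kind \code{"tumor_survival"}.
#' @param x target percent, one of 10, 25, 50, 75, 90.
#' @return an [EcxResult-class].
#' @export
computeIcx <- function(curve, x) {
  stopifnot(is(curve, "DoseResponseCurve"))
  if (curve@kind != "tumor_survival")
    stop("computeIcx() expects a tumor_survival curve", call. = FALSE)
  computeEcx(killFraction(curve), x)
}

#' Normalized area under a response curve
#'
#' Trapezoidal area over the interpolation axis from the lowest to the
#' highest tested dose, divided by the axis length — i.e. the mean
#' response over the tested range. A kill series with net growth yields a
#' negative value.
#'
#' @param series a [DoseResponseCurve-class] (any kind).
#' @return the mean response over the axis, a fraction.
#' @export
computeNormalizedAuc <- function(series) {
  stopifnot(is(series, "DoseResponseCurve"))
  a <- .axisCoords(series)
  n <- length(a)
  if (n < 2L) stop("AUC needs at least 2 doses", call. = FALSE)
  span <- a[n] - a[1L]
  if (span <= 0) stop("degenerate dose axis", call. = FALSE)
  v <- series@values
  sum(diff(a) * (v[-1L] + v[-n]) / 2) / span
}

## Segment slopes on the interpolation axis.
.segmentSlopes <- function(curve) {
  a <- .axisCoords(curve)
  diff(curve@values) / diff(a)
}

#' Slope through a series' own EC50
#'
#' The slope (response units per interpolation-axis unit, e.g. kill
#' fraction per log10-dose decade) of the piecewise-linear segment that
#' contains the series' own 50\% crossing. When the crossing precedes the
#' grid the first segment is used; when 50\% is never reached the steepest
#' segment slope stands in; a flat curve yields 0.
#'
#' @param series a [DoseResponseCurve-class] of kind \code{"tumor_kill"}
#'   or \code{"slice_toxicity"}.
#' @return the slope (0 for a flat curve).
#' @export
computeSlopeAtEc50 <- function(series) {
  stopifnot(is(series, "DoseResponseCurve"))
  if (length(series@doses) < 2L)
    stop("slope needs at least 2 doses", call. = FALSE)
  slopes <- .segmentSlopes(series)
  cr <- .firstCrossing(.axisCoords(series), series@values, 0.5)
  if (is.null(cr)) return(max(slopes))
  if (cr$belowRange) return(slopes[1L])
  slopes[cr$index - 1L]
}

#' Shape diagnostics of a tumor survival curve
#'
#' Reads off the quantities behind the three behavioral score parameters:
#' maximum growth relative to untreated (treatment-accelerated growth),
#' residual tumor at the top dose (incomplete kill), and a biphasic flag
#' for curves with rapid low-dose killing, little additional killing at
#' higher doses, and substantial residual tumor. The operational biphasic
#' rule: max kill over the lower half of the dose grid >= \code{lowKillMin}
#' AND (overall max kill - that low-half kill) <= \code{tailGainMax} AND
#' more than \code{remainingMin} percent tumor remaining at the top dose.
#'
#' @param object a [DoseResponseCurve-class] of kind
#'   \code{"tumor_survival"}.
#' @param lowKillMin minimum low-half kill for a biphasic call (default
#'   0.25).
#' @param tailGainMax maximum additional kill over the upper half (default
#'   0.10).
#' @param remainingMin minimum percent remaining at the top dose (default
#'   10).
#' @param ... unused.
#' @return a [CurveShape-class].
#' @export
setMethod("detectShape", "DoseResponseCurve",
          function(object, lowKillMin = 0.25, tailGainMax = 0.10,
                   remainingMin = 10, ...) {
  if (object@kind != "tumor_survival")
    stop("detectShape() requires a tumor_survival curve", call. = FALSE)
  s <- object@values
  n <- length(s)
  kill <- 1 - s
  lowHalf <- seq_len(ceiling(n / 2))
  remaining <- 100 * s[n]
  lowKill <- max(kill[lowHalf])
  biphasic <- (lowKill >= lowKillMin) &&
    (max(kill) - lowKill <= tailGainMax) &&
    (remaining > remainingMin)
  slope <- if (n >= 2L) computeSlopeAtEc50(killFraction(object)) else 0
  new("CurveShape", maxKill = max(kill), maxGrowthPercent = 100 * max(s),
      remainingAtMax = remaining, biphasic = biphasic, slopeAtEc50 = slope)
})

setMethod("show", "EcxResult", function(object) {
  lvl <- sprintf("EC%g", object@x)
  if (!object@reached) {
    cat(sprintf("%s: NR (not reached within the tested range)\n", lvl))
  } else if (object@belowRange) {
    cat(sprintf("%s: <= %g %s (crossing precedes the lowest tested dose)\n",
                lvl, object@dose, object@unit))
  } else {
    cat(sprintf("%s: %g %s\n", lvl, object@dose, object@unit))
  }
})

setMethod("show", "CurveShape", function(object) {
  cat(sprintf(
    "CurveShape: max kill %.3f | max growth %.1f%% | remaining %.1f%% | %s | slope@EC50 %.3f\n",
    object@maxKill, object@maxGrowthPercent, object@remainingAtMax,
    if (object@biphasic) "biphasic" else "not biphasic",
    object@slopeAtEc50))
})

#' Fig-3A-style ICx table for a set of curves
#'
#' @param curves named list of tumor survival curves; names are
#'   "tumor|drug" keys or arbitrary labels.
#' @param x percent levels to tabulate (default 50).
#' @return data.frame with tumor_id, drug_id, x, dose_at_x (NA when NR),
#'   reached, below_range.
#' @export
icxTable <- function(curves, x = 50) {
  rows <- lapply(names(curves), function(key) {
    ids <- strsplit(key, "|", fixed = TRUE)[[1L]]
    tumor <- ids[1L]
    drug <- if (length(ids) > 1L) ids[2L] else NA_character_
    do.call(rbind, lapply(x, function(xi) {
      r <- computeIcx(curves[[key]], xi)
      data.frame(tumor_id = tumor, drug_id = drug, x = xi,
                 dose_at_x = if (r@reached) r@dose else NA_real_,
                 reached = r@reached, below_range = r@belowRange,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
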