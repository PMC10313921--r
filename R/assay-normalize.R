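#' Construct a DoseResponseCurve
#'
#' @param doses strictly increasing positive dose grid.
#' @param values normalized response at each dose.
#' @param kind \code{"tumor_survival"}, \code{"tumor_kill"} or
#'   \code{"slice_toxicity"}.
#' @param unit dose unit, \code{"uM"} (micromolar) or \code{"Gy"}.
#' @param axis interpolation axis; defaults to \code{"log"} for uM and
#'   \code{"linear"} for Gy.
#' @param replicateN replicate count per dose.
#' @param replicateSem per-dose standard error of the mean.
#' @return a [DoseResponseCurve-class].
#' @examples
#' DoseResponseCurve(c(1, 10, 100), c(0.9, 0.5, 0.1), "tumor_survival")
#' @export
DoseResponseCurve <- function(doses, values,
                              kind = c("tumor_survival", "tumor_kill",
                                       "slice_toxicity"),
                              unit = c("uM", "Gy"), axis = NULL,
                              replicateN = NULL, replicateSem = NULL) {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  if (is.null(axis)) axis <- if (unit == "uM") "log" else "linear"
  ord <- order(doses)
  doses <- as.numeric(doses)[ord]
  values <- as.numeric(values)[ord]
  n <- length(doses)
  if (is.null(replicateN)) replicateN <- rep(0L, n)
  if (is.null(replicateSem)) replicateSem <- rep(NA_real_, n)
  new("DoseResponseCurve", doses = doses, values = values, kind = kind,
      unit = unit, axis = axis,
      replicateN = as.integer(replicateN)[ord],
      replicateSem = as.numeric(replicateSem)[ord])
}

#' @rdname DoseResponseCurve
#' @export
setMethod("doses", "DoseResponseCurve", function(object) object@doses)

#' @rdname DoseResponseCurve
#' @export
setMethod("respValues", "DoseResponseCurve", function(object) object@values)

#' @rdname DoseResponseCurve
#' @export
setMethod("curveKind", "DoseResponseCurve", function(object) object@kind)

#' @rdname DoseResponseCurve
#' @export
setMethod("doseUnit", "DoseResponseCurve", function(object) object@unit)

#' @rdname DoseResponseCurve
#' @export
setMethod("interpolationAxis", "DoseResponseCurve",
          function(object) object@axis)

setMethod("show", "DoseResponseCurve", function(object) {
  cat(sprintf("DoseResponseCurve (%s), %d doses [%g..%g %s], %s axis\n",
              object@kind, length(object@doses), min(object@doses),
              max(object@doses), object@unit, object@axis))
  cat("  values:", paste(signif(object@values, 3), collapse = " "), "\n")
})

## axis coordinates of a curve's dose grid
.axisCoords <- function(curve) {
  if (curve@axis == "log") log10(curve@doses) else curve@doses
}

.fromAxis <- function(coord, axis) if (axis == "log") 10^coord else coord

#' Construct an AssayDesign
#'
#' @param nDoses number of tested doses (>= 2).
#' @param nFociPerDose tumor foci per dose (>= 1).
#' @param doseUnit \code{"uM"} or \code{"Gy"}.
#' @param doseSpacing \code{"log"} or \code{"linear"}; defaults to log for
#'   uM and linear for Gy.
#' @return an [AssayDesign-class].
#' @export
AssayDesign <- function(nDoses = 6L, nFociPerDose = 4L,
                        doseUnit = c("uM", "Gy"), doseSpacing = NULL) {
  doseUnit <- match.arg(doseUnit)
  if (is.null(doseSpacing))
    doseSpacing <- if (doseUnit == "uM") "log" else "linear"
  new("AssayDesign", nDoses = as.integer(nDoses),
      nFociPerDose = as.integer(nFociPerDose), doseUnit = doseUnit,
      doseSpacing = doseSpacing)
}

.TUMOR_RAW_COLS <- c("focus_id", "tumor_id", "drug_id", "dose", "dose_unit",
                     "bli_end", "fluor_day1", "is_untreated_control")
.SLICE_RAW_COLS <- c("slice_id", "drug_id", "dose", "dose_unit", "pi_signal",
                     "role")

.checkColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.asLogicalFlag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

.validateRows <- function(ok, df, what, reason) {
  if (any(!ok)) {
    bad <- which(!ok)
    stop(sprintf("%s: %s at row(s) %s", what, reason,
                 paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
}

#' Read raw tumor measurements from CSV
#'
#' Expects the \code{tumor_raw.csv} dialect: comma-separated, header
#' mandatory, UTF-8, "." decimal, with columns focus_id, tumor_id, drug_id,
#' dose, dose_unit, bli_end, fluor_day1, is_untreated_control. Malformed
#' rows are errors, reported with row numbers.
#'
#' @param path path to the CSV file.
#' @return a validated data.frame.
#' @export
readTumorRaw <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  .checkColumns(df, .TUMOR_RAW_COLS, basename(path))
  if (nrow(df) == 0L)
    stop(sprintf("%s: no measurements", basename(path)), call. = FALSE)
  df$dose <- suppressWarnings(as.numeric(df$dose))
  df$bli_end <- suppressWarnings(as.numeric(df$bli_end))
  df$fluor_day1 <- suppressWarnings(as.numeric(df$fluor_day1))
  df$is_untreated_control <- .asLogicalFlag(df$is_untreated_control)
  what <- basename(path)
  .validateRows(is.finite(df$dose) & df$dose >= 0, df, what,
                "dose must be a non-negative number")
  .validateRows(is.finite(df$bli_end) & df$bli_end >= 0, df, what,
                "bli_end must be a non-negative number")
  .validateRows(is.finite(df$fluor_day1) & df$fluor_day1 > 0, df, what,
                "fluor_day1 must be a positive number")
  .validateRows(!(df$is_untreated_control & df$dose != 0), df, what,
                "untreated controls must have dose = 0")
  .validateRows(df$dose_unit %in% .DOSE_UNITS, df, what,
                "dose_unit must be 'uM' or 'Gy'")
  df
}

#' Read raw slice PI measurements from CSV
#'
#' Expects the \code{slice_raw.csv} dialect with columns slice_id, drug_id,
#' dose, dose_unit, pi_signal, role (treated | healthy_baseline |
#' dead_control).
#'
#' @param path path to the CSV file.
#' @return a validated data.frame.
#' @export
readSliceRaw <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  .checkColumns(df, .SLICE_RAW_COLS, basename(path))
  if (nrow(df) == 0L)
    stop(sprintf("%s: no measurements", basename(path)), call. = FALSE)
  df$dose <- suppressWarnings(as.numeric(df$dose))
  df$pi_signal <- suppressWarnings(as.numeric(df$pi_signal))
  what <- basename(path)
  .validateRows(is.finite(df$dose) & df$dose >= 0, df, what,
                "dose must be a non-negative number")
  .validateRows(is.finite(df$pi_signal) & df$pi_signal >= 0, df, what,
                "pi_signal must be a non-negative number")
  .validateRows(df$role %in% c("treated", "healthy_baseline", "dead_control"),
                df, what, "role must be treated/healthy_baseline/dead_control")
  .validateRows(df$dose_unit %in% .DOSE_UNITS, df, what,
                "dose_unit must be 'uM' or 'Gy'")
  df
}

.aggregateFun <- function(aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "mean") mean else stats::median
}

#' Normalize raw tumor measurements to a survival curve
#'
#' Each focus is normalized to its own day-one fluorescence
#' (\code{bli_end / fluor_day1}, size correction), replicates at a dose are
#' aggregated, and the result is divided by the aggregated ratio of the
#' untreated control group. Survival is deliberately not capped at 1:
#' treatment-accelerated growth (survival > 1) carries information used by
#' the growth-acceleration window.
#'
#' @param raw data.frame in the \code{tumor_raw.csv} dialect, restricted to
#'   one drug-tumor pair plus its untreated controls.
#' @param aggregate replicate aggregation, \code{"mean"} (default; screens
#'   report mean +/- SEM) or \code{"median"}.
#' @param axis interpolation axis override (default chosen from the unit).
#' @return a [DoseResponseCurve-class] of kind \code{"tumor_survival"}.
#' @examples
#' raw <- data.frame(
#'   focus_id = paste0("f", 1:8), tumor_id = "T1", drug_id = "D1",
#'   dose = c(0, 0, 1, 1, 10, 10, 100, 100), dose_unit = "uM",
#'   bli_end = c(100, 100, 80, 80, 50, 50, 10, 10), fluor_day1 = 100,
#'   is_untreated_control = c(TRUE, TRUE, rep(FALSE, 6)))
#' normalizeTumorSurvival(raw)
#' @export
normalizeTumorSurvival <- function(raw, aggregate = c("mean", "median"),
                                   axis = NULL) {
  .checkColumns(raw, .TUMOR_RAW_COLS, "tumor measurements")
  agg <- .aggregateFun(aggregate)
  raw$is_untreated_control <- .asLogicalFlag(raw$is_untreated_control)
  ctrl <- raw[raw$is_untreated_control, , drop = FALSE]
  trt <- raw[!raw$is_untreated_control, , drop = FALSE]
  if (nrow(ctrl) == 0L)
    stop("no untreated controls: cannot normalize tumor survival",
         call. = FALSE)
  if (nrow(trt) == 0L)
    stop("no treated measurements", call. = FALSE)
  if (any(trt$dose <= 0))
    stop("treated foci must have positive doses", call. = FALSE)
  if (any(trt$fluor_day1 <= 0) || any(ctrl$fluor_day1 <= 0))
    stop("fluor_day1 must be positive for every focus", call. = FALSE)
  unit <- unique(c(trt$dose_unit))
  if (length(unit) != 1L)
    stop("mixed dose units within one curve", call. = FALSE)
  ctrlRatio <- agg(ctrl$bli_end / ctrl$fluor_day1)
  if (ctrlRatio <= 0)
    stop("untreated control ratio is non-positive", call. = FALSE)
  ratio <- trt$bli_end / trt$fluor_day1
  byDose <- split(ratio / ctrlRatio, trt$dose)
  doseGrid <- as.numeric(names(byDose))
  ord <- order(doseGrid)
  s <- vapply(byDose, agg, numeric(1))[ord]
  n <- vapply(byDose, length, integer(1))[ord]
  sem <- vapply(byDose, function(v) {
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))[ord]
  DoseResponseCurve(doseGrid[ord], s, kind = "tumor_survival", unit = unit,
                    axis = axis, replicateN = n, replicateSem = sem)
}

#' Normalize raw slice PI measurements to a toxicity curve
#'
#' Toxicity at each dose is the treated PI signal rescaled between the
#' healthy-baseline mean (0) and the dead-control mean (1):
#' \code{tox(d) = clamp((PI(d) - PI_healthy) / (PI_dead - PI_healthy), 0, 1)}.
#' PI below the healthy baseline is measurement noise, not negative death,
#' hence the clamp.
#'
#' @param raw data.frame in the \code{slice_raw.csv} dialect restricted to
#'   one drug (plus shared anchors).
#' @param aggregate replicate aggregation (\code{"mean"} default).
#' @param axis interpolation axis override.
#' @return a [DoseResponseCurve-class] of kind \code{"slice_toxicity"}.
#' @export
normalizeToxicity <- function(raw, aggregate = c("mean", "median"),
                              axis = NULL) {
  .checkColumns(raw, .SLICE_RAW_COLS, "slice measurements")
  agg <- .aggregateFun(aggregate)
  healthy <- raw$pi_signal[raw$role == "healthy_baseline"]
  dead <- raw$pi_signal[raw$role == "dead_control"]
  trt <- raw[raw$role == "treated", , drop = FALSE]
  if (length(healthy) == 0L || length(dead) == 0L)
    stop("toxicity normalization needs >= 1 healthy_baseline and >= 1 dead_control slice",
         call. = FALSE)
  if (nrow(trt) == 0L)
    stop("no treated slices", call. = FALSE)
  if (any(trt$dose <= 0))
    stop("treated slices must have positive doses", call. = FALSE)
  unit <- unique(trt$dose_unit)
  if (length(unit) != 1L)
    stop("mixed dose units within one curve", call. = FALSE)
  h <- mean(healthy)
  d <- mean(dead)
  if (d <= h)
    stop("degenerate anchors: dead-control PI must exceed healthy baseline",
         call. = FALSE)
  idx <- pmin(pmax((trt$pi_signal - h) / (d - h), 0), 1)
  byDose <- split(idx, trt$dose)
  doseGrid <- as.numeric(names(byDose))
  ord <- order(doseGrid)
  tox <- vapply(byDose, agg, numeric(1))[ord]
  n <- vapply(byDose, length, integer(1))[ord]
  sem <- vapply(byDose, function(v) {
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))[ord]
  DoseResponseCurve(doseGrid[ord], tox, kind = "slice_toxicity", unit = unit,
                    axis = axis, replicateN = n, replicateSem = sem)
}

#' Per-slice normalized death index
#'
#' The slice-level analogue of [normalizeToxicity()], used by QC: each
#' slice's PI signal rescaled between the healthy and dead anchors and
#' clamped to [0, 1].
#'
#' @param pi numeric PI signals.
#' @param healthyMean,deadMean anchor means; \code{deadMean} must exceed
#'   \code{healthyMean}.
#' @return numeric death indices in [0, 1].
#' @export
deathIndex <- function(pi, healthyMean, deadMean) {
  if (!is.finite(healthyMean) || !is.finite(deadMean) ||
      deadMean <= healthyMean)
    stop("degenerate anchors: dead-control PI must exceed healthy baseline",
         call. = FALSE)
  pmin(pmax((pi - healthyMean) / (deadMean - healthyMean), 0), 1)
}

#' Kill fraction of a tumor survival curve
#'
#' \code{k(d) = 1 - s(d)} per dose. Not clipped below 0: negative kill
#' encodes treatment-accelerated growth.
#'
#' @param object a [DoseResponseCurve-class] of kind
#'   \code{"tumor_survival"}.
#' @return a [DoseResponseCurve-class] of kind \code{"tumor_kill"}.
#' @export
setMethod("killFraction", "DoseResponseCurve", function(object) {
  if (object@kind != "tumor_survival")
    stop("killFraction() requires a tumor_survival curve", call. = FALSE)
  new("DoseResponseCurve", doses = object@doses, values = 1 - object@values,
      kind = "tumor_kill", unit = object@unit, axis = object@axis,
      replicateN = object@replicateN, replicateSem = object@replicateSem)
})

#' Survival curve from a kill series
#'
#' Inverse of [killFraction()].
#'
#' @param object a [DoseResponseCurve-class] of kind \code{"tumor_kill"}.
#' @return a [DoseResponseCurve-class] of kind \code{"tumor_survival"}.
#' @rdname killFraction
#' @export
survivalFromKill <- function(object) {
  if (object@kind != "tumor_kill")
    stop("survivalFromKill() requires a tumor_kill curve", call. = FALSE)
  new("DoseResponseCurve", doses = object@doses, values = 1 - object@values,
      kind = "tumor_survival", unit = object@unit, axis = object@axis,
      replicateN = object@replicateN, replicateSem = object@replicateSem)
}
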