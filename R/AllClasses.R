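#' @import methods
NULL

## Canonical window order used everywhere a length-11 window/weight vector
## appears. Changing this order is an API break.
.WINDOW_NAMES <- c("max_kill", "ec10", "ec25", "ec50", "ec75", "ec90",
                   "slope", "auc", "growth", "biphasic", "incomplete")

.ECX_LEVELS <- c(10, 25, 50, 75, 90)

.DOSE_UNITS <- c("uM", "Gy")

#' DoseResponseCurve: a normalized dose-response series
#'
#' Holds one normalized response series indexed by a strictly increasing
#' positive dose grid. Three kinds are supported: \code{"tumor_survival"}
#' (fraction of untreated tumor signal; may exceed 1 when treatment
#' accelerates growth), \code{"tumor_kill"} (1 - survival; may be negative),
#' and \code{"slice_toxicity"} (fraction of the dead-control PI signal,
#' always in [0, 1]).
#'
#' Interpolation between doses happens on the curve's \code{axis}:
#' \code{"log"} (log10 dose; the default for molar concentrations, where
#' screens use log-spaced doses) or \code{"linear"} (the default for
#' radiation doses in Gy).
#'
#' @slot doses strictly increasing positive numeric dose grid.
#' @slot values numeric response at each dose.
#' @slot kind one of \code{"tumor_survival"}, \code{"tumor_kill"},
#'   \code{"slice_toxicity"}.
#' @slot unit dose unit, \code{"uM"} or \code{"Gy"}.
#' @slot axis interpolation axis, \code{"log"} or \code{"linear"}.
#' @slot replicateN integer replicate count per dose (0 when unknown).
#' @slot replicateSem numeric per-dose standard error (NA when unknown).
#'
#' @seealso [DoseResponseCurve()] for the user constructor.
#' @exportClass DoseResponseCurve
setClass("DoseResponseCurve",
  representation(
    doses = "numeric",
    values = "numeric",
    kind = "character",
    unit = "character",
    axis = "character",
    replicateN = "integer",
    replicateSem = "numeric"
  )
)

setValidity("DoseResponseCurve", function(object) {
  msg <- character()
  d <- object@doses
  v <- object@values
  if (length(d) < 1L) msg <- c(msg, "curve must have at least one dose")
  if (any(!is.finite(d)) || any(d <= 0))
    msg <- c(msg, "doses must be finite and strictly positive")
  if (length(d) > 1L && any(diff(d) <= 0))
    msg <- c(msg, "doses must be strictly increasing")
  if (length(v) != length(d))
    msg <- c(msg, "values and doses must have equal length")
  if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
  if (length(object@kind) != 1L ||
      !object@kind %in% c("tumor_survival", "tumor_kill", "slice_toxicity"))
    msg <- c(msg, "kind must be tumor_survival, tumor_kill or slice_toxicity")
  else {
    if (object@kind == "slice_toxicity" &&
        length(v) && (min(v) < 0 || max(v) > 1))
      msg <- c(msg, "slice_toxicity values must lie in [0, 1]")
    if (object@kind == "tumor_survival" && length(v) && min(v) < 0)
      msg <- c(msg, "tumor_survival values must be >= 0")
    if (object@kind == "tumor_kill" && length(v) && max(v) > 1 + 1e-12)
      msg <- c(msg, "tumor_kill values cannot exceed 1")
  }
  if (length(object@unit) != 1L || !object@unit %in% .DOSE_UNITS)
    msg <- c(msg, "unit must be 'uM' or 'Gy'")
  if (length(object@axis) != 1L || !object@axis %in% c("log", "linear"))
    msg <- c(msg, "axis must be 'log' or 'linear'")
  if (length(object@replicateN) != length(d) ||
      length(object@replicateSem) != length(d))
    msg <- c(msg, "replicateN and replicateSem must match the dose grid")
  if (length(msg)) msg else TRUE
})

#' EcxResult: an interpolated ECx/ICx estimate with NR semantics
#'
#' @slot x target response percent (10, 25, 50, 75 or 90).
#' @slot dose dose at which the response first crosses x/100, or \code{NA}
#'   when not reached (NR).
#' @slot reached \code{FALSE} when the curve never attains x/100 within the
#'   tested range (the "NR" convention of screening reports).
#' @slot belowRange \code{TRUE} when the crossing precedes the lowest tested
#'   dose; the lowest dose is then reported rather than extrapolating.
#' @slot unit dose unit.
#' @exportClass EcxResult
setClass("EcxResult",
  representation(x = "numeric", dose = "numeric", reached = "logical",
                 belowRange = "logical", unit = "character")
)

setValidity("EcxResult", function(object) {
  if (!object@reached && !is.na(object@dose))
    return("dose must be NA when the target level is not reached")
  TRUE
})

#' CurveShape: shape diagnostics of a tumor survival curve
#'
#' @slot maxKill maximum kill fraction over the dose grid.
#' @slot maxGrowthPercent 100 x max survival (>100 means treatment-
#'   accelerated growth).
#' @slot remainingAtMax 100 x survival at the highest dose.
#' @slot biphasic rapid low-dose killing followed by a high-dose plateau
#'   with substantial residual tumor.
#' @slot slopeAtEc50 kill slope through the curve's EC50, per interpolation
#'   axis unit.
#' @exportClass CurveShape
setClass("CurveShape",
  representation(maxKill = "numeric", maxGrowthPercent = "numeric",
                 remainingAtMax = "numeric", biphasic = "logical",
                 slopeAtEc50 = "numeric")
)

#' TherapeuticWindows: the eleven window parameters for one interaction
#'
#' Each window lives on the [-1, +1] scale: values toward +1 mean tumor
#' kill outpaces normal-tissue toxicity, values toward -1 mean the slice is
#' harmed while the tumor thrives. Windows 9-11 (growth, biphasic,
#' incomplete kill) are ternary in {-1, 0, +1}.
#'
#' @slot values named numeric(11) in canonical order
#'   (max_kill, ec10, ec25, ec50, ec75, ec90, slope, auc, growth, biphasic,
#'   incomplete).
#' @slot nrFlags named logical(5): \code{TRUE} when the tumor ECx was not
#'   reached and the shortfall fallback was used.
#' @slot tumorId,drugId identifiers (NA when scoring free-standing curves).
#' @exportClass TherapeuticWindows
setClass("TherapeuticWindows",
  representation(values = "numeric", nrFlags = "logical",
                 tumorId = "character", drugId = "character")
)

setValidity("TherapeuticWindows", function(object) {
  msg <- character()
  v <- object@values
  if (length(v) != 11L || !identical(names(v), .WINDOW_NAMES))
    msg <- c(msg, "values must be a named numeric(11) in canonical order")
  else {
    if (any(!is.finite(v)) || min(v) < -1 - 1e-12 || max(v) > 1 + 1e-12)
      msg <- c(msg, "all windows must lie in [-1, +1]")
    tern <- v[c("growth", "biphasic", "incomplete")]
    if (!all(tern %in% c(-1, 0, 1)))
      msg <- c(msg, "growth/biphasic/incomplete windows must be in {-1, 0, +1}")
  }
  if (length(object@nrFlags) != 5L ||
      !identical(names(object@nrFlags), paste0("ec", .ECX_LEVELS)))
    msg <- c(msg, "nrFlags must be a named logical(5) for ec10..ec90")
  if (length(msg)) msg else TRUE
})

#' WeightVector: the eleven DSS parameter weights
#'
#' Defaults are the published split: max kill 10%, EC10/EC25 5% each,
#' EC50 10%, EC75/EC90 5% each, slope 10%, AUC 35%, growth 5%, biphasic 5%,
#' incomplete kill 5%. Weights must sum to 1.
#'
#' @slot weights named numeric(11) summing to 1 within 1e-12.
#' @exportClass WeightVector
setClass("WeightVector", representation(weights = "numeric"))

setValidity("WeightVector", function(object) {
  w <- object@weights
  if (length(w) != 11L || !identical(names(w), .WINDOW_NAMES))
    return("weights must be a named numeric(11) in canonical window order")
  if (any(!is.finite(w)) || any(w < 0))
    return("weights must be finite and non-negative")
  if (abs(sum(w) - 1) > 1e-12)
    return("weights must sum to 1 (within 1e-12)")
  TRUE
})

#' DssResult: the drug sensitivity score for one drug-tumor pair
#'
#' @slot tumorId,drugId identifiers.
#' @slot dss score on the [-100, +100] scale; exactly
#'   \code{100 * sum(weights * windows)}.
#' @slot windows the [TherapeuticWindows-class] behind the score.
#' @slot weights the [WeightVector-class] used.
#' @exportClass DssResult
setClass("DssResult",
  representation(tumorId = "character", drugId = "character",
                 dss = "numeric", windows = "TherapeuticWindows",
                 weights = "WeightVector")
)

setValidity("DssResult", function(object) {
  if (length(object@dss) != 1L || !is.finite(object@dss))
    return("dss must be a single finite number")
  if (abs(object@dss) > 100 + 1e-9)
    return("dss must lie in [-100, +100]")
  TRUE
})

#' DssMatrix: drugs x tumors score array with missing entries
#'
#' Untested drug-tumor pairs stay \code{NA} (the gray boxes of a screening
#' heatmap) and are preserved through reporting.
#'
#' @slot scores numeric matrix, drugs as rows, tumors as columns, NA for
#'   untested pairs.
#' @slot results named list of [DssResult-class], keyed "drug\\tumor".
#' @slot cohorts named character per tumor (e.g. cell line vs patient
#'   tissue), carried into waterfall output.
#' @exportClass DssMatrix
setClass("DssMatrix",
  representation(scores = "matrix", results = "list", cohorts = "character")
)

setValidity("DssMatrix", function(object) {
  s <- object@scores
  if (length(s) && (is.null(rownames(s)) || is.null(colnames(s))))
    return("scores matrix must carry drug rownames and tumor colnames")
  TRUE
})

#' QcReport: batch-level slice viability QC decision
#'
#' @slot batchId batch identifier.
#' @slot nSampled number of slices sampled for the PI check.
#' @slot meanIndex mean normalized death index of the sampled slices, in
#'   [0, 1] (0 = healthy baseline, 1 = dead control).
#' @slot historyMean,historySd reference mean and dispersion over prior
#'   batches (NA when no usable history).
#' @slot pass overall decision.
#' @slot reasons human-readable reasons when failing (empty on pass).
#' @slot tauAbs,kappa thresholds used (echoed for the report).
#' @exportClass QcReport
setClass("QcReport",
  representation(batchId = "character", nSampled = "integer",
                 meanIndex = "numeric", historyMean = "numeric",
                 historySd = "numeric", pass = "logical",
                 reasons = "character", tauAbs = "numeric", kappa = "numeric")
)

#' HillParams: generative parameters for a synthetic dose-response curve
#'
#' The simulator draws survival from a Hill form
#' \code{s(d) = growthFactor * (floor + (1 - floor) / (1 + (d/ec50)^hill))};
#' an optional \code{plateauKill} cap replaces the kill by
#' \code{min(1 - s0, plateauKill)}, producing biphasic shapes. Toxicity
#' curves use the complement of the same form with \code{growthFactor = 1}.
#'
#' @slot floor residual survival fraction in [0, 1].
#' @slot ec50 dose of half-maximal effect (> 0).
#' @slot hill Hill slope coefficient (> 0).
#' @slot growthFactor >= 1 multiplier for treatment-accelerated growth.
#' @slot plateauKill optional kill cap in (0, 1]; NA disables it.
#' @exportClass HillParams
setClass("HillParams",
  representation(floor = "numeric", ec50 = "numeric", hill = "numeric",
                 growthFactor = "numeric", plateauKill = "numeric")
)

setValidity("HillParams", function(object) {
  msg <- character()
  if (!is.finite(object@ec50) || object@ec50 <= 0)
    msg <- c(msg, "ec50 must be > 0")
  if (!is.finite(object@floor) || object@floor < 0 || object@floor > 1)
    msg <- c(msg, "floor must lie in [0, 1]")
  if (!is.finite(object@hill) || object@hill <= 0)
    msg <- c(msg, "hill must be > 0")
  if (!is.finite(object@growthFactor) || object@growthFactor < 1)
    msg <- c(msg, "growthFactor must be >= 1")
  if (!is.na(object@plateauKill) &&
      (object@plateauKill <= 0 || object@plateauKill > 1))
    msg <- c(msg, "plateauKill must lie in (0, 1] or be NA")
  if (length(msg)) msg else TRUE
})

#' AssayDesign: layout of a slice drug screen
#'
#' @slot nDoses number of tested doses (default 6).
#' @slot nFociPerDose tumor foci per dose (default 4).
#' @slot doseUnit \code{"uM"} or \code{"Gy"}.
#' @slot doseSpacing \code{"log"} (3 decades around the reference EC50) or
#'   \code{"linear"}.
#' @exportClass AssayDesign
setClass("AssayDesign",
  representation(nDoses = "integer", nFociPerDose = "integer",
                 doseUnit = "character", doseSpacing = "character")
)

setValidity("AssayDesign", function(object) {
  msg <- character()
  if (object@nDoses < 2L) msg <- c(msg, "nDoses must be >= 2")
  if (object@nFociPerDose < 1L) msg <- c(msg, "nFociPerDose must be >= 1")
  if (!object@doseUnit %in% .DOSE_UNITS) msg <- c(msg, "doseUnit must be 'uM' or 'Gy'")
  if (!object@doseSpacing %in% c("log", "linear"))
    msg <- c(msg, "doseSpacing must be 'log' or 'linear'")
  if (length(msg)) msg else TRUE
})

#' SyntheticAssay: a simulated screen with known ground truth
#'
#' Bundles raw measurement tables in the input CSV dialects together with
#' the noiseless generative curves, the analytic oracle windows/DSS, and
#' the seed, so pipeline output can be checked against truth.
#'
#' @slot design the [AssayDesign-class].
#' @slot tumorRaw data.frame in the \code{tumor_raw.csv} dialect.
#' @slot sliceRaw data.frame in the \code{slice_raw.csv} dialect.
#' @slot truthTumor,truthTox noiseless [DoseResponseCurve-class] objects on
#'   a dense grid.
#' @slot truthWindows oracle [TherapeuticWindows-class].
#' @slot truthDss oracle DSS (numeric).
#' @slot tumorParams,toxParams the generative [HillParams-class].
#' @slot seed integer seed that reproduces the assay byte-identically.
#' @exportClass SyntheticAssay
setClass("SyntheticAssay",
  representation(design = "AssayDesign", tumorRaw = "data.frame",
                 sliceRaw = "data.frame", truthTumor = "DoseResponseCurve",
                 truthTox = "DoseResponseCurve",
                 truthWindows = "TherapeuticWindows", truthDss = "numeric",
                 tumorParams = "HillParams", toxParams = "HillParams",
                 seed = "integer")
)
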