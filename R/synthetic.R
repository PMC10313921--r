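#' Construct HillParams
#'
#' @param ec50 dose of half-maximal effect (> 0).
#' @param hill Hill slope coefficient (> 0).
#' @param floor residual survival fraction in [0, 1] (0 = complete kill
#'   achievable, for toxicity curves 1 - floor is the maximal toxicity).
#' @param growthFactor >= 1 multiplier modelling treatment-accelerated
#'   growth (tumor curves only).
#' @param plateauKill optional kill cap in (0, 1] producing biphasic
#'   shapes; NA disables.
#' @return a [HillParams-class].
#' @export
HillParams <- function(ec50, hill = 1, floor = 0, growthFactor = 1,
                       plateauKill = NA_real_) {
  new("HillParams", floor = as.numeric(floor), ec50 = as.numeric(ec50),
      hill = as.numeric(hill), growthFactor = as.numeric(growthFactor),
      plateauKill = as.numeric(plateauKill))
}

setMethod("show", "HillParams", function(object) {
  cat(sprintf(
    "HillParams: ec50 %g, hill %g, floor %g, growthFactor %g%s\n",
    object@ec50, object@hill, object@floor, object@growthFactor,
    if (is.na(object@plateauKill)) ""
    else sprintf(", plateauKill %g", object@plateauKill)))
})

#' Closed-form survival and toxicity of the generative model
#'
#' Survival: \code{s(d) = growthFactor * (floor + (1 - floor) /
#' (1 + (d / ec50)^hill))}; with a \code{plateauKill} cap the kill is
#' capped first, \code{s(d) = growthFactor * max(s0(d), 1 - plateauKill)}.
#' Toxicity is the complement of the same saturating form with
#' \code{growthFactor} ignored: \code{tox(d) = min(1 - s0(d), plateauKill)}.
#'
#' @param d numeric doses (>= 0).
#' @param params a [HillParams-class].
#' @return numeric fractions.
#' @export
hillSurvival <- function(d, params) {
  stopifnot(is(params, "HillParams"))
  validObject(params)
  s0 <- params@floor +
    (1 - params@floor) / (1 + (d / params@ec50)^params@hill)
  if (!is.na(params@plateauKill))
    s0 <- pmax(s0, 1 - params@plateauKill)
  params@growthFactor * s0
}

#' @rdname hillSurvival
#' @export
hillToxicity <- function(d, params) {
  stopifnot(is(params, "HillParams"))
  validObject(params)
  s0 <- params@floor +
    (1 - params@floor) / (1 + (d / params@ec50)^params@hill)
  tox <- 1 - s0
  if (!is.na(params@plateauKill)) tox <- pmin(tox, params@plateauKill)
  tox
}

#' Default dose grid for a design
#'
#' Log spacing: \code{nDoses} doses over 3 decades centred (in log10) on
#' the reference EC50, mirroring small-molecule screening practice.
#' Linear spacing (radiation): evenly spaced from \code{ec50ref / 3} to
#' \code{2 * ec50ref}.
#'
#' @param design an [AssayDesign-class].
#' @param ec50ref reference dose the grid is anchored on (typically the
#'   tumor EC50).
#' @return numeric dose grid.
#' @export
designDoses <- function(design, ec50ref) {
  stopifnot(is(design, "AssayDesign"))
  if (design@doseSpacing == "log")
    ec50ref * 10^seq(-1.5, 1.5, length.out = design@nDoses)
  else
    seq(ec50ref / 3, 2 * ec50ref, length.out = design@nDoses)
}

## Multiplicative log-normal noise with mean 1 and coefficient of
## variation cv (bioluminescence is positive and right-skewed).
.lnormNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## Fixed instrument/biology constants of the simulator; arbitrary scales
## that normalization must cancel.
.SIM_FLUOR_MEAN <- 1000    # day-1 fluorescence units per focus
.SIM_FLUOR_CV <- 0.2       # engraftment size variability
.SIM_BLI_PER_FLUOR <- 50   # photons/s per fluorescence unit at survival 1
.SIM_PI_HEALTHY <- 100     # healthy-baseline PI signal
.SIM_PI_DEAD <- 1100       # dead-control PI signal
.SIM_N_ANCHORS <- 6L       # healthy and dead anchor slices each
.SIM_SLICES_PER_DOSE <- 2L # treated PI slices per dose (6 doses -> n = 12)

#' Simulate one synthetic screen with known ground truth
#'
#' Draws raw tumor-focus and slice measurements from the Hill generative
#' model under multiplicative log-normal replicate noise, back-constructed
#' so [normalizeTumorSurvival()] and [normalizeToxicity()] recover the
#' closed-form curves in expectation. Also computes the noiseless truth
#' curves on a dense grid and the analytic oracle windows/DSS
#' ([oracleWindows()]). The same seed and parameters reproduce the assay
#' byte-identically.
#'
#' @param tumor [HillParams-class] of the tumor survival curve.
#' @param tox [HillParams-class] of the slice toxicity curve
#'   (\code{growthFactor} must be 1).
#' @param design an [AssayDesign-class].
#' @param noiseCv replicate noise coefficient of variation (>= 0).
#' @param seed integer seed.
#' @param doses optional explicit dose grid (default [designDoses()]
#'   anchored on the tumor EC50).
#' @param tumorId,drugId identifiers written into the raw tables.
#' @return a [SyntheticAssay-class].
#' @examples
#' a <- simulateAssay(HillParams(ec50 = 1), HillParams(ec50 = 20, floor = 0.5),
#'                    noiseCv = 0, seed = 1)
#' round(a@truthDss)
#' @export
simulateAssay <- function(tumor, tox, design = AssayDesign(),
                          noiseCv = 0.10, seed = 1L, doses = NULL,
                          tumorId = "T1", drugId = "D1") {
  stopifnot(is(tumor, "HillParams"), is(tox, "HillParams"),
            is(design, "AssayDesign"))
  validObject(tumor); validObject(tox); validObject(design)
  if (tox@growthFactor != 1)
    stop("toxicity curves cannot have a growth factor", call. = FALSE)
  if (!is.finite(noiseCv) || noiseCv < 0)
    stop("noiseCv must be >= 0", call. = FALSE)
  if (is.null(doses)) doses <- designDoses(design, tumor@ec50)
  if (length(doses) != design@nDoses || any(diff(doses) <= 0))
    stop("doses must be a strictly increasing grid of length nDoses",
         call. = FALSE)
  seed <- as.integer(seed)
  set.seed(seed)

  nF <- design@nFociPerDose
  sTrue <- hillSurvival(doses, tumor)
  toxTrue <- hillToxicity(doses, tox)

  ## tumor foci: treated (one block per dose) + untreated controls
  doseCol <- c(rep(doses, each = nF), rep(0, nF))
  survCol <- c(rep(sTrue, each = nF), rep(1, nF))
  nTot <- length(doseCol)
  fluor <- .SIM_FLUOR_MEAN * .lnormNoise(nTot, .SIM_FLUOR_CV)
  bli <- fluor * .SIM_BLI_PER_FLUOR * survCol * .lnormNoise(nTot, noiseCv)
  tumorRaw <- data.frame(
    focus_id = sprintf("%s_%s_f%02d", tumorId, drugId, seq_len(nTot)),
    tumor_id = tumorId, drug_id = drugId, dose = doseCol,
    dose_unit = design@doseUnit, bli_end = bli, fluor_day1 = fluor,
    is_untreated_control = doseCol == 0, stringsAsFactors = FALSE)

  ## slices: treated per dose + healthy/dead anchors
  nS <- .SIM_SLICES_PER_DOSE
  nA <- .SIM_N_ANCHORS
  trtDose <- rep(doses, each = nS)
  trtPi <- (.SIM_PI_HEALTHY +
            rep(toxTrue, each = nS) * (.SIM_PI_DEAD - .SIM_PI_HEALTHY)) *
    .lnormNoise(length(trtDose), noiseCv)
  healthyPi <- .SIM_PI_HEALTHY * .lnormNoise(nA, noiseCv)
  deadPi <- .SIM_PI_DEAD * .lnormNoise(nA, noiseCv)
  sliceRaw <- data.frame(
    slice_id = sprintf("%s_s%02d", drugId,
                       seq_len(length(trtDose) + 2L * nA)),
    drug_id = drugId,
    dose = c(trtDose, rep(0, 2L * nA)),
    dose_unit = design@doseUnit,
    pi_signal = c(trtPi, healthyPi, deadPi),
    role = c(rep("treated", length(trtDose)),
             rep("healthy_baseline", nA), rep("dead_control", nA)),
    stringsAsFactors = FALSE)

  axis <- if (design@doseSpacing == "log") "log" else "linear"
  dense <- .denseGrid(min(doses), max(doses), axis)
  truthTumor <- DoseResponseCurve(dense, hillSurvival(dense, tumor),
                                  kind = "tumor_survival",
                                  unit = design@doseUnit, axis = axis)
  truthTox <- DoseResponseCurve(dense, hillToxicity(dense, tox),
                                kind = "slice_toxicity",
                                unit = design@doseUnit, axis = axis)
  oracle <- oracleWindows(tumor, tox, design, doses = doses,
                          tumorId = tumorId, drugId = drugId)
  new("SyntheticAssay", design = design, tumorRaw = tumorRaw,
      sliceRaw = sliceRaw, truthTumor = truthTumor, truthTox = truthTox,
      truthWindows = oracle$windows, truthDss = oracle$dss,
      tumorParams = tumor, toxParams = tox, seed = seed)
}

.denseGrid <- function(dmin, dmax, axis, n = 10000L) {
  if (axis == "log") 10^seq(log10(dmin), log10(dmax), length.out = n)
  else seq(dmin, dmax, length.out = n)
}

## Brute-force crossing scan on a dense grid: first index at/above the
## target level. Deliberately independent of .firstCrossing()'s
## interpolation arithmetic.
.denseScanCross <- function(values, target) {
  hit <- which(values >= target)
  if (length(hit) == 0L) NULL else hit[1L]
}

#' Analytic dense-grid oracle for windows and DSS
#'
#' Evaluates the closed-form generative curves on a 10^4-point dense grid
#' spanning the design's dose range and computes the eleven windows and
#' the DSS by direct brute-force scans (first grid index at each level,
#' mean response for AUC, finite-difference slope at the 50\% crossing).
#' This is the ground truth that pipeline output on the sparse 6-dose
#' grid is checked against; it shares the window definitions but none of
#' the interpolation code.
#'
#' @inheritParams simulateAssay
#' @param weights a [WeightVector-class] for the DSS.
#' @return list with elements \code{windows} ([TherapeuticWindows-class])
#'   and \code{dss} (numeric).
#' @export
oracleWindows <- function(tumor, tox, design = AssayDesign(), doses = NULL,
                          weights = defaultWeights(),
                          tumorId = NA_character_, drugId = NA_character_) {
  stopifnot(is(tumor, "HillParams"), is(tox, "HillParams"))
  validObject(tumor); validObject(tox)
  if (is.null(doses)) doses <- designDoses(design, tumor@ec50)
  axis <- if (design@doseSpacing == "log") "log" else "linear"
  d <- .denseGrid(min(doses), max(doses), axis)
  a <- if (axis == "log") log10(d) else d
  n <- length(d)
  s <- hillSurvival(d, tumor)
  k <- 1 - s
  tx <- hillToxicity(d, tox)

  clamp1 <- function(x) pmin(pmax(x, -1), 1)
  ecxW <- numeric(5)
  nr <- logical(5)
  for (j in seq_along(.ECX_LEVELS)) {
    t <- .ECX_LEVELS[j] / 100
    i <- .denseScanCross(k, t)
    if (is.null(i)) {
      nr[j] <- TRUE
      ecxW[j] <- clamp1(max(k) - t - tx[n])
    } else {
      ecxW[j] <- clamp1(k[i] - tx[i])
    }
  }
  names(nr) <- paste0("ec", .ECX_LEVELS)

  ## finite-difference slope at a series' own 50% crossing; steepest
  ## local slope when not reached, first-step slope when below range
  slopeAt50 <- function(v) {
    dv <- diff(v) / diff(a)
    i <- .denseScanCross(v, 0.5)
    if (is.null(i)) return(max(dv))
    if (i == 1L) return(dv[1L])
    dv[i - 1L]
  }
  mT <- slopeAt50(k)
  mO <- slopeAt50(tx)
  denom <- abs(mT) + abs(mO)
  slopeW <- if (denom > 0) (mT - mO) / denom else {
    tR <- !is.null(.denseScanCross(k, 0.5))
    oR <- !is.null(.denseScanCross(tx, 0.5))
    if (tR && !oR) 1 else if (!tR && oR) -1 else 0
  }

  aucW <- clamp1(mean(k) - mean(tx))
  maxKillW <- clamp1(k[n] - tx[n])

  maxGrowth <- 100 * max(s)
  remaining <- 100 * s[n]
  ## the biphasic rule is defined on the tested dose grid ("lower half of
  ## the dose grid"), so the oracle evaluates it on the closed-form values
  ## at the design doses
  kGrid <- 1 - hillSurvival(doses, tumor)
  lowHalf <- seq_len(ceiling(length(doses) / 2))
  lowKill <- max(kGrid[lowHalf])
  biphasic <- lowKill >= 0.25 && (max(kGrid) - lowKill) <= 0.10 &&
    remaining > 10
  growthW <- if (maxGrowth <= 125) 1 else if (maxGrowth <= 150) 0 else -1
  biphasicW <- if (biphasic) -1 else 1
  incompleteW <- if (remaining < 10) 1 else if (remaining <= 25) 0 else -1

  v <- c(maxKillW, ecxW, slopeW, aucW, growthW, biphasicW, incompleteW)
  names(v) <- .WINDOW_NAMES
  w <- new("TherapeuticWindows", values = v, nrFlags = nr,
           tumorId = as.character(tumorId), drugId = as.character(drugId))
  list(windows = w, dss = 100 * sum(weights@weights * v))
}

#' Random screening scenario for calibration runs
#'
#' Draws one (tumor, toxicity) Hill parameter pair from ranges typical of
#' small-molecule slice screens: tumor EC50 log-uniform over a decade
#' around 1 uM, Hill slope 0.8-2.2, residual survival 0-0.35, occasional
#' (10\%) growth acceleration up to 1.6x and occasional (10\%) plateau
#' cap; toxicity EC50 shifted 0-1.2 decades above the tumor EC50 with
#' maximal toxicity 0.1-0.7. Draws from the current RNG stream.
#'
#' @return list with [HillParams-class] elements \code{tumor} and
#'   \code{tox}.
#' @export
randomScenario <- function() {
  tumor <- HillParams(
    ec50 = 10^stats::runif(1, -0.5, 0.5),
    hill = stats::runif(1, 0.8, 2.2),
    floor = stats::runif(1, 0, 0.35),
    growthFactor = if (stats::runif(1) < 0.1)
      stats::runif(1, 1.1, 1.6) else 1,
    plateauKill = if (stats::runif(1) < 0.1)
      stats::runif(1, 0.3, 0.6) else NA_real_)
  tox <- HillParams(
    ec50 = tumor@ec50 * 10^stats::runif(1, 0, 1.2),
    hill = stats::runif(1, 0.8, 2.0),
    floor = stats::runif(1, 0.3, 0.9))
  list(tumor = tumor, tox = tox)
}

#' The default scenario pack
#'
#' Five named (tumor, tox) parameter pairs spanning the qualitative curve
#' classes a screen encounters: \code{sensitive} (potent kill, late
#' toxicity), \code{resistant} (little kill in range), \code{growth}
#' (treatment-accelerated growth), \code{biphasic} (plateaued kill) and
#' \code{toxic_only} (slice dies, tumor survives).
#'
#' @return named list of lists with elements \code{tumor} and \code{tox}.
#' @export
scenarioPack <- function() {
  list(
    sensitive = list(tumor = HillParams(ec50 = 0.5, hill = 1.5),
                     tox = HillParams(ec50 = 30, hill = 1.5, floor = 0.4)),
    resistant = list(tumor = HillParams(ec50 = 500, hill = 1, floor = 0.5),
                     tox = HillParams(ec50 = 50, hill = 1, floor = 0.6)),
    growth = list(tumor = HillParams(ec50 = 200, hill = 1, floor = 0.8,
                                     growthFactor = 1.6),
                  tox = HillParams(ec50 = 100, hill = 1, floor = 0.7)),
    biphasic = list(tumor = HillParams(ec50 = 0.3, hill = 1.5,
                                       plateauKill = 0.35),
                    tox = HillParams(ec50 = 20, hill = 1.2, floor = 0.5)),
    toxic_only = list(tumor = HillParams(ec50 = 1000, hill = 1, floor = 0.9),
                      tox = HillParams(ec50 = 0.8, hill = 1.5, floor = 0.1))
  )
}
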