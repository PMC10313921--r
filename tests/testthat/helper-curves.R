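## Shared fixtures: curve constructors and an independent dense-scan
## brute force used to cross-check the interpolation metrics.

DOSES6 <- 10^seq(-1, 1.5, length.out = 6)

killCurve <- function(values, doses = 10^(seq_along(values) - 1),
                      unit = "uM") {
  DoseResponseCurve(doses, values, kind = "tumor_kill", unit = unit)
}

survCurve <- function(values, doses = 10^(seq_along(values) - 1),
                      unit = "uM") {
  DoseResponseCurve(doses, values, kind = "tumor_survival", unit = unit)
}

toxCurve <- function(values, doses = 10^(seq_along(values) - 1),
                     unit = "uM") {
  DoseResponseCurve(doses, values, kind = "slice_toxicity", unit = unit)
}

## Brute-force ECx on a piecewise-linear curve: sample the interpolant on
## a dense axis grid and scan for the first point at/above the level.
## Independent of computeEcx()'s crossing arithmetic.
bruteEcx <- function(curve, x, n = 10000L) {
  a <- if (interpolationAxis(curve) == "log") log10(doses(curve))
       else doses(curve)
  grid <- seq(a[1L], a[length(a)], length.out = n)
  v <- approx(a, respValues(curve), xout = grid)$y
  hit <- which(v >= x / 100)
  if (length(hit) == 0L)
    return(list(reached = FALSE, dose = NA_real_, belowRange = FALSE))
  coord <- grid[hit[1L]]
  list(reached = TRUE,
       dose = if (interpolationAxis(curve) == "log") 10^coord else coord,
       belowRange = hit[1L] == 1L,
       step = grid[2L] - grid[1L])
}

## Random valid survival/toxicity pair on a shared log grid.
randomCurvePair <- function(nDoses = 6L) {
  d <- 10^seq(-1, 1.5, length.out = nDoses)
  s <- runif(nDoses, 0, 1.8)
  tox <- runif(nDoses, 0, 1)
  list(surv = DoseResponseCurve(d, s, "tumor_survival"),
       tox = DoseResponseCurve(d, tox, "slice_toxicity"))
}

## Raw tumor table builder: one drug-tumor pair with given per-focus
## ratios (bli/fluor) per dose plus untreated controls.
rawTumorTable <- function(doseValues, ratios, ctrlRatios,
                          tumorId = "T1", drugId = "D1", unit = "uM") {
  stopifnot(length(doseValues) == length(ratios))
  fluor <- 100
  trt <- data.frame(
    focus_id = sprintf("f%03d", seq_along(doseValues)),
    tumor_id = tumorId, drug_id = drugId, dose = doseValues,
    dose_unit = unit, bli_end = unlist(ratios) * fluor,
    fluor_day1 = fluor, is_untreated_control = FALSE,
    stringsAsFactors = FALSE)
  ctrl <- data.frame(
    focus_id = sprintf("c%03d", seq_along(ctrlRatios)),
    tumor_id = tumorId, drug_id = drugId, dose = 0, dose_unit = unit,
    bli_end = ctrlRatios * fluor, fluor_day1 = fluor,
    is_untreated_control = TRUE, stringsAsFactors = FALSE)
  rbind(trt, ctrl)
}

rawSliceTable <- function(doseValues, piValues, healthy = 100,
                          dead = 1100, drugId = "D1", unit = "uM") {
  trt <- data.frame(
    slice_id = sprintf("s%03d", seq_along(doseValues)), drug_id = drugId,
    dose = doseValues, dose_unit = unit, pi_signal = piValues,
    role = "treated", stringsAsFactors = FALSE)
  anch <- data.frame(
    slice_id = c(sprintf("h%02d", seq_along(healthy)),
                 sprintf("d%02d", seq_along(dead))),
    drug_id = drugId, dose = 0, dose_unit = unit,
    pi_signal = c(healthy, dead),
    role = rep(c("healthy_baseline", "dead_control"),
               c(length(healthy), length(dead))),
    stringsAsFactors = FALSE)
  rbind(trt, anch)
}
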