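#' Score every drug-tumor pair in a raw measurement bundle
#'
#' End-to-end: normalizes each (tumor, drug) block of the tumor table
#' against that tumor's untreated controls, normalizes each drug's slice
#' PI block against the shared healthy/dead anchors, computes the eleven
#' therapeutic windows and the DSS, and assembles the score matrix.
#'
#' @param tumorRaw data.frame in the \code{tumor_raw.csv} dialect
#'   (multiple drugs/tumors allowed; untreated controls are matched by
#'   tumor_id).
#' @param sliceRaw data.frame in the \code{slice_raw.csv} dialect
#'   (treated slices matched by drug_id; healthy/dead anchors shared).
#' @param weights a [WeightVector-class].
#' @param aggregate replicate aggregation ("mean" or "median").
#' @param axis interpolation axis override (NULL = by unit).
#' @param cohorts optional named character vector tumor_id -> cohort tag.
#' @param lowKillMin,tailGainMax,remainingMin biphasic-rule thresholds.
#' @return list with elements \code{matrix} ([DssMatrix-class]),
#'   \code{results} (list of [DssResult-class]), \code{windows} (list of
#'   [TherapeuticWindows-class]), \code{curves} (named list of survival
#'   curves keyed "tumor|drug"), \code{toxCurves} (named by drug).
#' @export
scoreAssays <- function(tumorRaw, sliceRaw, weights = defaultWeights(),
                        aggregate = "mean", axis = NULL,
                        cohorts = character(), lowKillMin = 0.25,
                        tailGainMax = 0.10, remainingMin = 10) {
  .checkColumns(tumorRaw, .TUMOR_RAW_COLS, "tumor measurements")
  .checkColumns(sliceRaw, .SLICE_RAW_COLS, "slice measurements")
  tumorRaw$is_untreated_control <- .asLogicalFlag(tumorRaw$is_untreated_control)
  trt <- tumorRaw[!tumorRaw$is_untreated_control, , drop = FALSE]
  if (nrow(trt) == 0L)
    stop("no treated tumor measurements", call. = FALSE)
  anchors <- sliceRaw[sliceRaw$role != "treated", , drop = FALSE]

  toxCurves <- list()
  for (drug in unique(sliceRaw$drug_id[sliceRaw$role == "treated"])) {
    block <- rbind(
      sliceRaw[sliceRaw$role == "treated" & sliceRaw$drug_id == drug, ,
               drop = FALSE],
      anchors)
    toxCurves[[drug]] <- normalizeToxicity(block, aggregate = aggregate,
                                           axis = axis)
  }

  pairs <- unique(trt[, c("tumor_id", "drug_id")])
  results <- list()
  windowsList <- list()
  curves <- list()
  for (i in seq_len(nrow(pairs))) {
    tumorId <- pairs$tumor_id[i]
    drugId <- pairs$drug_id[i]
    block <- rbind(
      trt[trt$tumor_id == tumorId & trt$drug_id == drugId, , drop = FALSE],
      tumorRaw[tumorRaw$is_untreated_control &
                 tumorRaw$tumor_id == tumorId, , drop = FALSE])
    surv <- normalizeTumorSurvival(block, aggregate = aggregate,
                                   axis = axis)
    if (is.null(toxCurves[[drugId]]))
      stop(sprintf("no slice toxicity measurements for drug '%s'", drugId),
           call. = FALSE)
    w <- computeAllWindows(surv, toxCurves[[drugId]], tumorId = tumorId,
                           drugId = drugId, lowKillMin = lowKillMin,
                           tailGainMax = tailGainMax,
                           remainingMin = remainingMin)
    key <- paste(tumorId, drugId, sep = "|")
    curves[[key]] <- surv
    windowsList[[key]] <- w
    results[[key]] <- aggregateDss(w, weights)
  }
  list(matrix = buildDssMatrix(results, cohorts = cohorts),
       results = results, windows = windowsList, curves = curves,
       toxCurves = toxCurves)
}

#' Write a scored bundle to an output directory
#'
#' Emits \code{windows.csv} (eleven windows + NR flags per pair),
#' \code{icx.csv} (ICx table with empty cells for NR), \code{dss_matrix.csv}
#' (drugs x tumors, empty cells for untested pairs), \code{waterfall.csv}
#' and \code{run_config.json} (weights and settings echo, with NR
#' annotations).
#'
#' @param scored result of [scoreAssays()].
#' @param outDir output directory (created if needed).
#' @param config list echoed into \code{run_config.json}.
#' @param icxLevels percent levels for the ICx table.
#' @return invisibly, the paths written.
#' @export
writeScoreBundle <- function(scored, outDir, config = list(),
                             icxLevels = 50) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    windows = file.path(outDir, "windows.csv"),
    icx = file.path(outDir, "icx.csv"),
    matrix = file.path(outDir, "dss_matrix.csv"),
    waterfall = file.path(outDir, "waterfall.csv"),
    config = file.path(outDir, "run_config.json"))

  utils::write.csv(windowsTable(scored$windows), paths["windows"],
                   row.names = FALSE)
  utils::write.csv(icxTable(scored$curves, x = icxLevels), paths["icx"],
                   row.names = FALSE, na = "")

  m <- scoreMatrix(scored$matrix)
  mdf <- data.frame(drug_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(mdf, paths["matrix"], row.names = FALSE, na = "")
  utils::write.csv(waterfallOrder(scored$matrix), paths["waterfall"],
                   row.names = FALSE, na = "")

  wts <- if (length(scored$results))
    weightValues(scored$results[[1L]]@weights) else
      weightValues(defaultWeights())
  nrAnn <- lapply(scored$windows, function(w) as.list(nrFlags(w)))
  jsonlite::write_json(
    list(config = config, weights = as.list(wts), nr_flags = nrAnn),
    paths["config"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Score raw CSV inputs and write the full output bundle
#'
#' The \code{score} entry point: reads and validates \code{tumor_raw.csv}
#' and \code{slice_raw.csv}, scores every drug-tumor pair and writes the
#' report bundle. Validation failures are errors naming the offending
#' rows.
#'
#' @param tumorCsv,sliceCsv input CSV paths.
#' @param outDir output directory.
#' @param weights a [WeightVector-class] or numeric(11) override.
#' @param aggregate,axis,cohorts,lowKillMin,tailGainMax,remainingMin
#'   passed to [scoreAssays()].
#' @param icxLevels percent levels for the ICx table.
#' @return the [scoreAssays()] result, invisibly.
#' @export
runScore <- function(tumorCsv, sliceCsv, outDir, weights = defaultWeights(),
                     aggregate = "mean", axis = NULL, cohorts = character(),
                     lowKillMin = 0.25, tailGainMax = 0.10,
                     remainingMin = 10, icxLevels = 50) {
  if (!is(weights, "WeightVector")) weights <- WeightVector(weights)
  tumorRaw <- readTumorRaw(tumorCsv)
  sliceRaw <- readSliceRaw(sliceCsv)
  scored <- scoreAssays(tumorRaw, sliceRaw, weights = weights,
                        aggregate = aggregate, axis = axis,
                        cohorts = cohorts, lowKillMin = lowKillMin,
                        tailGainMax = tailGainMax,
                        remainingMin = remainingMin)
  writeScoreBundle(scored, outDir,
                   config = list(tumor_csv = tumorCsv,
                                 slice_csv = sliceCsv,
                                 aggregate = aggregate,
                                 axis = if (is.null(axis)) "auto" else axis,
                                 biphasic_rule = list(
                                   low_kill_min = lowKillMin,
                                   tail_gain_max = tailGainMax,
                                   remaining_min = remainingMin)),
                   icxLevels = icxLevels)
  invisible(scored)
}

#' Simulate a scenario pack and write it as an input bundle
#'
#' The \code{simulate} entry point: generates one synthetic assay per
#' scenario (default: the five-scenario pack), concatenates them into the
#' \code{tumor_raw.csv} / \code{slice_raw.csv} dialects consumed by
#' [runScore()], and writes \code{truth.json} with the generative
#' parameters, oracle windows and oracle DSS per scenario. Each scenario
#' is tagged as its own drug against a common synthetic tumor id.
#' Deterministic under \code{seed}.
#'
#' @param outDir output directory.
#' @param scenarios named list of lists with [HillParams-class] elements
#'   \code{tumor} and \code{tox} (default [scenarioPack()]).
#' @param design an [AssayDesign-class].
#' @param noiseCv replicate noise CV.
#' @param seed integer master seed; per-scenario seeds are derived from
#'   it.
#' @param tumorId tumor identifier used in the bundle.
#' @return invisibly, the list of [SyntheticAssay-class] objects.
#' @export
runSimulate <- function(outDir, scenarios = scenarioPack(),
                        design = AssayDesign(), noiseCv = 0.10, seed = 1L,
                        tumorId = "SYN1") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  assays <- list()
  tumorTabs <- list()
  sliceTabs <- list()
  truth <- list()
  for (i in seq_along(scenarios)) {
    nm <- names(scenarios)[i]
    sc <- scenarios[[i]]
    a <- simulateAssay(sc$tumor, sc$tox, design = design,
                       noiseCv = noiseCv, seed = seed + i - 1L,
                       tumorId = tumorId, drugId = nm)
    assays[[nm]] <- a
    tr <- a@tumorRaw
    ## one shared untreated control block per tumor: keep controls only
    ## from the first scenario
    if (i > 1L) tr <- tr[!tr$is_untreated_control, , drop = FALSE]
    tumorTabs[[nm]] <- tr
    sr <- a@sliceRaw
    if (i > 1L) sr <- sr[sr$role == "treated", , drop = FALSE]
    sliceTabs[[nm]] <- sr
    truth[[nm]] <- list(
      seed = a@seed,
      tumor_params = list(ec50 = sc$tumor@ec50, hill = sc$tumor@hill,
                          floor = sc$tumor@floor,
                          growth_factor = sc$tumor@growthFactor,
                          plateau_kill = sc$tumor@plateauKill),
      tox_params = list(ec50 = sc$tox@ec50, hill = sc$tox@hill,
                        floor = sc$tox@floor),
      oracle_windows = as.list(windowValues(a@truthWindows)),
      oracle_nr = as.list(nrFlags(a@truthWindows)),
      oracle_dss = a@truthDss)
  }
  tumorRaw <- do.call(rbind, tumorTabs)
  sliceRaw <- do.call(rbind, sliceTabs)
  utils::write.csv(tumorRaw, file.path(outDir, "tumor_raw.csv"),
                   row.names = FALSE)
  utils::write.csv(sliceRaw, file.path(outDir, "slice_raw.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, noise_cv = noiseCv,
         design = list(n_doses = design@nDoses,
                       n_foci_per_dose = design@nFociPerDose,
                       dose_unit = design@doseUnit,
                       dose_spacing = design@doseSpacing),
         scenarios = truth),
    file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(assays)
}

#' Run batch QC from a CSV and write the report
#'
#' The \code{qc} entry point: reads a \code{slice_raw.csv}-dialect file of
#' sampled slices plus anchors, applies [qcBatch()] against an optional
#' history CSV (per-batch summaries with a \code{mean_index} column),
#' writes \code{qc_report.csv} and returns the report.
#'
#' @param sliceCsv sampled-slice CSV path.
#' @param outDir output directory.
#' @param historyCsv optional history CSV path.
#' @param batchId batch identifier.
#' @param tauAbs,kappa thresholds, see [qcBatch()].
#' @return the [QcReport-class], invisibly.
#' @export
runQc <- function(sliceCsv, outDir, historyCsv = NULL, batchId = "batch",
                  tauAbs = 0.25, kappa = 3) {
  sampled <- readSliceRaw(sliceCsv)
  history <- if (!is.null(historyCsv))
    utils::read.csv(historyCsv, stringsAsFactors = FALSE) else NULL
  report <- qcBatch(sampled, history = history, batchId = batchId,
                    tauAbs = tauAbs, kappa = kappa)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(qcReportTable(report),
                   file.path(outDir, "qc_report.csv"), row.names = FALSE)
  invisible(report)
}
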