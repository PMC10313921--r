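#' Batch-level slice viability QC
#'
#' Mirrors the screening practice of pulling a handful of untreated slices
#' from every batch for a PI cell-death check: each sampled slice's PI
#' signal is converted to a normalized death index between the healthy
#' baseline (0) and the dead control (1), and the batch passes only when
#' the mean index is low in absolute terms AND consistent with previous
#' batches.
#'
#' Decision rule: pass iff \code{mean index <= tauAbs} (default 0.25) and,
#' when at least two historical batch summaries exist, \code{mean index <=
#' historyMean + kappa * historySd} (default kappa = 3; one-sided — only
#' excess death fails). Thresholds are conventions of this package (the
#' source procedure is qualitative) and are echoed in the report.
#'
#' @param sampled data.frame in the \code{slice_raw.csv} dialect: the
#'   sampled untreated slices with \code{role = "treated"} (dose 0 is
#'   fine), plus \code{healthy_baseline} and \code{dead_control} anchor
#'   rows.
#' @param history optional data.frame of prior batch summaries with a
#'   \code{mean_index} column (one row per prior batch), e.g. read from
#'   \code{qc_history.csv}.
#' @param batchId identifier recorded in the report.
#' @param tauAbs absolute ceiling on the mean death index.
#' @param kappa historical z-score ceiling.
#' @return a [QcReport-class].
#' @examples
#' sampled <- data.frame(
#'   slice_id = paste0("s", 1:8), drug_id = NA, dose = 0, dose_unit = "uM",
#'   pi_signal = c(rep(120, 6), 100, 1100),
#'   role = c(rep("treated", 6), "healthy_baseline", "dead_control"))
#' qcBatch(sampled, batchId = "B1")
#' @export
qcBatch <- function(sampled, history = NULL, batchId = "batch",
                    tauAbs = 0.25, kappa = 3) {
  .checkColumns(sampled, .SLICE_RAW_COLS, "QC slice measurements")
  healthy <- sampled$pi_signal[sampled$role == "healthy_baseline"]
  dead <- sampled$pi_signal[sampled$role == "dead_control"]
  qc <- sampled[sampled$role == "treated", , drop = FALSE]
  if (nrow(qc) == 0L)
    stop("QC needs at least one sampled slice", call. = FALSE)
  if (length(healthy) == 0L || length(dead) == 0L)
    stop("QC needs healthy_baseline and dead_control anchors", call. = FALSE)
  idx <- deathIndex(qc$pi_signal, mean(healthy), mean(dead))
  m <- mean(idx)
  histMean <- NA_real_
  histSd <- NA_real_
  if (!is.null(history) && nrow(history) >= 2L) {
    if (!"mean_index" %in% names(history))
      stop("history must carry a mean_index column", call. = FALSE)
    histMean <- mean(history$mean_index)
    histSd <- stats::sd(history$mean_index)
  }
  reasons <- character()
  if (m > tauAbs)
    reasons <- c(reasons, sprintf(
      "mean death index %.3f exceeds absolute threshold %.3f", m, tauAbs))
  if (is.finite(histSd) && histSd > 0 && m > histMean + kappa * histSd)
    reasons <- c(reasons, sprintf(
      "mean death index %.3f exceeds historical mean %.3f + %g sd (%.3f)",
      m, histMean, kappa, histMean + kappa * histSd))
  new("QcReport", batchId = as.character(batchId), nSampled = nrow(qc),
      meanIndex = m, historyMean = histMean, historySd = histSd,
      pass = length(reasons) == 0L, reasons = reasons, tauAbs = tauAbs,
      kappa = kappa)
}

setMethod("show", "QcReport", function(object) {
  cat(sprintf("QcReport [%s]: %s — mean death index %.3f (n = %d)\n",
              object@batchId, if (object@pass) "PASS" else "FAIL",
              object@meanIndex, object@nSampled))
  if (!object@pass)
    cat(paste0("  - ", object@reasons, collapse = "\n"), "\n")
})

#' One-row data.frame view of a QC report
#'
#' @param report a [QcReport-class].
#' @return data.frame suitable for \code{qc_report.csv}.
#' @export
qcReportTable <- function(report) {
  stopifnot(is(report, "QcReport"))
  data.frame(batch_id = report@batchId, n_sampled = report@nSampled,
             mean_index = report@meanIndex,
             history_mean = report@historyMean,
             history_sd = report@historySd, tau_abs = report@tauAbs,
             kappa = report@kappa, pass = report@pass,
             reasons = paste(report@reasons, collapse = "; "),
             stringsAsFactors = FALSE)
}
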