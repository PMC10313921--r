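#' The published DSS weight vector
#'
#' Max kill 10\%, EC10 5\%, EC25 5\%, EC50 10\%, EC75 5\%, EC90 5\%, slope
#' 10\%, AUC 35\%, growth 5\%, biphasic 5\%, incomplete kill 5\%.
#'
#' @return a [WeightVector-class].
#' @export
defaultWeights <- function() {
  WeightVector(c(max_kill = 0.10, ec10 = 0.05, ec25 = 0.05, ec50 = 0.10,
                 ec75 = 0.05, ec90 = 0.05, slope = 0.10, auc = 0.35,
                 growth = 0.05, biphasic = 0.05, incomplete = 0.05))
}

#' Construct a WeightVector
#'
#' @param weights numeric(11) summing to 1; if unnamed, taken in canonical
#'   window order (max_kill, ec10, ec25, ec50, ec75, ec90, slope, auc,
#'   growth, biphasic, incomplete).
#' @return a [WeightVector-class].
#' @export
WeightVector <- function(weights) {
  weights <- as.numeric(unlist(weights))
  if (length(weights) != 11L)
    stop("a weight vector has exactly 11 entries", call. = FALSE)
  names(weights) <- .WINDOW_NAMES
  new("WeightVector", weights = weights)
}

#' @rdname WeightVector
#' @param object a [WeightVector-class].
#' @export
setMethod("weightValues", "WeightVector", function(object) object@weights)

setMethod("show", "WeightVector", function(object) {
  cat("WeightVector (fractions of DSS):\n")
  print(object@weights)
})

#' Aggregate eleven windows into a drug sensitivity score
#'
#' \code{DSS = 100 * sum(w_i * window_i)}: every weighted parameter added
#' together and placed on the [-100, +100] scale, where +100 describes an
#' agent with maximal tumor kill and no slice toxicity and -100 one under
#' which the tumor thrives while the slice dies.
#'
#' @param windows a [TherapeuticWindows-class].
#' @param weights a [WeightVector-class] (defaults to the published
#'   weights).
#' @return a [DssResult-class].
#' @examples
#' w <- TherapeuticWindows(rep(1, 11))
#' dssScore(aggregateDss(w))  # 100
#' @export
aggregateDss <- function(windows, weights = defaultWeights()) {
  stopifnot(is(windows, "TherapeuticWindows"))
  if (!is(weights, "WeightVector")) weights <- WeightVector(weights)
  validObject(weights)
  dss <- 100 * sum(weights@weights * windows@values)
  new("DssResult", tumorId = windows@tumorId, drugId = windows@drugId,
      dss = dss, windows = windows, weights = weights)
}

#' @rdname DssResult
#' @param object a [DssResult-class].
#' @export
setMethod("dssScore", "DssResult", function(object) object@dss)

setMethod("show", "DssResult", function(object) {
  cat(sprintf("DssResult: %s x %s, DSS = %.0f\n", object@drugId,
              object@tumorId, object@dss))
})

.dssKey <- function(drug, tumor) paste(drug, tumor, sep = "\r")

#' Assemble per-pair scores into a drugs x tumors matrix
#'
#' Row/column ordering is the stable order of first appearance in
#' \code{results}; untested drug-tumor pairs stay \code{NA} and are
#' preserved through reporting (the gray boxes of a screening heatmap).
#'
#' @param results list of [DssResult-class] objects, keyed uniquely by
#'   (drug, tumor).
#' @param cohorts optional named character vector mapping tumor_id to a
#'   cohort tag (e.g. "cell_line" or "patient_tissue").
#' @return a [DssMatrix-class].
#' @export
buildDssMatrix <- function(results, cohorts = character()) {
  stopifnot(is.list(results))
  drugs <- character()
  tumors <- character()
  seen <- character()
  for (r in results) {
    stopifnot(is(r, "DssResult"))
    key <- .dssKey(r@drugId, r@tumorId)
    if (key %in% seen)
      stop(sprintf("duplicate (drug, tumor) pair: (%s, %s)", r@drugId,
                   r@tumorId), call. = FALSE)
    seen <- c(seen, key)
    if (!r@drugId %in% drugs) drugs <- c(drugs, r@drugId)
    if (!r@tumorId %in% tumors) tumors <- c(tumors, r@tumorId)
  }
  scores <- matrix(NA_real_, nrow = length(drugs), ncol = length(tumors),
                   dimnames = list(drugs, tumors))
  resList <- list()
  for (r in results) {
    scores[r@drugId, r@tumorId] <- r@dss
    resList[[.dssKey(r@drugId, r@tumorId)]] <- r
  }
  coh <- as.character(cohorts)
  names(coh) <- names(cohorts)
  new("DssMatrix", scores = scores, results = resList, cohorts = coh)
}

#' @rdname DssMatrix
#' @param object a [DssMatrix-class].
#' @export
setMethod("scoreMatrix", "DssMatrix", function(object) object@scores)

setMethod("show", "DssMatrix", function(object) {
  cat(sprintf("DssMatrix: %d drug(s) x %d tumor(s), %d score(s), %d missing\n",
              nrow(object@scores), ncol(object@scores),
              sum(!is.na(object@scores)), sum(is.na(object@scores))))
  print(round(object@scores))
})

#' Waterfall ordering of a score matrix
#'
#' All present scores sorted descending (ties broken lexicographically by
#' drug then tumor), with the cohort tag carried through — the layout of a
#' cross-panel waterfall plot.
#'
#' @param matrix a [DssMatrix-class] with at least one present entry.
#' @return data.frame with columns drug_id, tumor_id, dss, cohort.
#' @export
waterfallOrder <- function(matrix) {
  stopifnot(is(matrix, "DssMatrix"))
  s <- matrix@scores
  present <- which(!is.na(s), arr.ind = TRUE)
  if (nrow(present) == 0L)
    stop("waterfall ordering needs at least one present score", call. = FALSE)
  df <- data.frame(
    drug_id = rownames(s)[present[, 1L]],
    tumor_id = colnames(s)[present[, 2L]],
    dss = s[present],
    stringsAsFactors = FALSE)
  df$cohort <- if (length(matrix@cohorts))
    unname(matrix@cohorts[df$tumor_id]) else NA_character_
  df <- df[order(-df$dss, df$drug_id, df$tumor_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Score difference between two results for the same drug
#'
#' \code{dssScore(b) - dssScore(a)}; the primary/recurrent-tumor
#' comparison use case (how many points a drug gained or lost between two
#' tumors from the same patient).
#'
#' @param a,b [DssResult-class] objects for the same drug.
#' @return numeric score difference.
#' @export
dssDelta <- function(a, b) {
  stopifnot(is(a, "DssResult"), is(b, "DssResult"))
  if (!identical(a@drugId, b@drugId))
    stop(sprintf("dssDelta() compares the same drug; got '%s' and '%s'",
                 a@drugId, b@drugId), call. = FALSE)
  b@dss - a@dss
}
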