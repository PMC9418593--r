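#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' TapCohort: tap streams plus subject metadata
#'
#' Container for a cohort of smartphone tappigraphy recordings. Each stream is
#' a strictly increasing vector of touchscreen interaction timestamps in
#' milliseconds from the start of that subject's recording; metadata carries
#' age, gender code (0 male, 1 female), screen size, cohort label and the
#' number of distinct recording days.
#'
#' @slot streams named list of numeric timestamp vectors (ms), one per subject.
#' @slot subjects \code{DataFrame} with one row per subject and columns
#'   \code{subject_id}, \code{age_years}, \code{gender_code},
#'   \code{screen_size}, \code{cohort_label}, \code{recording_days}.
#'
#' @aliases TapCohort-class
#' @exportClass TapCohort
setClass("TapCohort",
  representation(streams = "list", subjects = "DataFrame"))

setValidity("TapCohort", function(object) {
  msg <- character()
  req <- c("subject_id", "age_years", "gender_code", "screen_size",
           "cohort_label", "recording_days")
  missing_cols <- setdiff(req, colnames(object@subjects))
  if (length(missing_cols))
    msg <- c(msg, paste("subjects lacks columns:",
                        paste(missing_cols, collapse = ", ")))
  if (!identical(names(object@streams),
                 as.character(object@subjects$subject_id)))
    msg <- c(msg, "stream names must equal subjects$subject_id, in order")
  if (!length(msg)) {
    bad <- vapply(object@streams,
                  function(ts) length(ts) > 0 && any(diff(ts) <= 0),
                  logical(1))
    if (any(bad))
      msg <- c(msg, paste("non-increasing timestamps in subject(s):",
                          paste(names(object@streams)[bad], collapse = ", ")))
    gc_ok <- all(object@subjects$gender_code %in% c(0, 1))
    if (!gc_ok) msg <- c(msg, "gender_code must be 0 or 1")
    if (any(object@subjects$age_years <= 0))
      msg <- c(msg, "age_years must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' JIDGrid: joint interval distribution on a 50 x 50 log10 grid
#'
#' Probability mass of consecutive inter-touch interval pairs
#' (ITI at k on rows, ITI at k+1 on columns), estimated by 2D Gaussian kernel
#' density in log10-millisecond space and discretised at the grid centers.
#'
#' @slot mass numeric matrix (default 50 x 50), non-negative, summing to 1.
#' @slot gridCenters numeric vector of log10-ms cell centers per axis.
#' @slot bandwidth Gaussian kernel bandwidth in log10-ms units.
#' @slot nPairs number of interval pairs the estimate is based on.
#'
#' @aliases JIDGrid-class
#' @exportClass JIDGrid
setClass("JIDGrid",
  representation(mass = "matrix", gridCenters = "numeric",
                 bandwidth = "numeric", nPairs = "integer"))

setValidity("JIDGrid", function(object) {
  msg <- character()
  n <- length(object@gridCenters)
  if (!all(dim(object@mass) == c(n, n)))
    msg <- c(msg, "mass must be square with dim = length(gridCenters)")
  if (any(object@mass < 0)) msg <- c(msg, "mass entries must be >= 0")
  if (object@nPairs > 0L && abs(sum(object@mass) - 1) > 1e-9)
    msg <- c(msg, "mass must sum to 1 (within 1e-9)")
  if (object@bandwidth <= 0) msg <- c(msg, "bandwidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' NormativeModel: cross-validated gradient-boosted age model
#'
#' Bundle of the 10 fold models of the healthy-aging regression, the fold
#' assignment of the training subjects, the hyperparameters, the feature
#' ordering, and the accumulation window the training features used.
#'
#' @slot foldModels list of fitted xgboost boosters, one per fold.
#' @slot foldAssignment named integer vector: subject_id -> fold index.
#' @slot hyperparams list, see \code{\link{modelHyperparams}}.
#' @slot featureNames character vector fixing the model's feature ordering.
#' @slot windowDays accumulation window (days) the training features used.
#' @slot seed integer seed the fold construction and fit used.
#'
#' @aliases NormativeModel-class
#' @exportClass NormativeModel
setClass("NormativeModel",
  representation(foldModels = "list", foldAssignment = "integer",
                 hyperparams = "list", featureNames = "character",
                 windowDays = "numeric", seed = "integer"))

setValidity("NormativeModel", function(object) {
  msg <- character()
  k <- length(object@foldModels)
  if (k < 2L) msg <- c(msg, "need at least 2 fold models")
  if (!all(object@foldAssignment %in% seq_len(k)))
    msg <- c(msg, "fold assignment indexes outside the fold model list")
  if (is.null(names(object@foldAssignment)))
    msg <- c(msg, "foldAssignment must be named by subject_id")
  if (length(msg)) msg else TRUE
})

#' AttributionMap: Shapley attributions per subject and per JID cell
#'
#' Additive per-feature attributions (years) for each subject's age
#' prediction, plus population aggregates with positive and negative
#' contributions separated and mapped back onto the JID plane.
#'
#' @slot perSubject numeric matrix subjects x features, in the bundle's
#'   feature ordering.
#' @slot baseValue per-subject expected model output (years).
#' @slot prediction per-subject model prediction the attributions decompose.
#' @slot positiveMap,negativeMap 50 x 50 population-mean maps of the
#'   positive (>= 0) and negative (<= 0) JID-cell attributions.
#' @slot covariateSummary data.frame of mean positive/negative attribution
#'   for the non-JID covariates.
#'
#' @aliases AttributionMap-class
#' @exportClass AttributionMap
setClass("AttributionMap",
  representation(perSubject = "matrix", baseValue = "numeric",
                 prediction = "numeric", positiveMap = "matrix",
                 negativeMap = "matrix", covariateSummary = "data.frame"))

setValidity("AttributionMap", function(object) {
  msg <- character()
  if (nrow(object@perSubject) != length(object@baseValue))
    msg <- c(msg, "one base value per subject required")
  resid <- abs(object@baseValue + rowSums(object@perSubject) -
               object@prediction)
  if (length(resid) && max(resid) > 1e-6)
    msg <- c(msg, "additivity violated: base + sum(attributions) != prediction")
  if (any(object@positiveMap < 0)) msg <- c(msg, "positiveMap must be >= 0")
  if (any(object@negativeMap > 0)) msg <- c(msg, "negativeMap must be <= 0")
  if (length(msg)) msg else TRUE
})

#' DeviationReport: advanced behavioral age in a patient cohort
#'
#' Holds the per-model median prediction errors of the patients, the
#' bootstrap age-matched healthy null distribution of median errors, their
#' two-sample t-test, the patient MAE, and the per-patient robust regression
#' of predicted on real age.
#'
#' @slot patientMedians numeric, one median error per fold model (years).
#' @slot nullMedians numeric, one median error per bootstrap iteration.
#' @slot tStatistic,pValue two-sample t-test between the two sets.
#' @slot patientMAE mean absolute prediction error over patients (years).
#' @slot gapYears mean(patientMedians) - mean(nullMedians).
#' @slot robustFit list: slope, intercept, r2, t, p, df of the robust
#'   regression of per-patient predicted age on real age.
#' @slot windowDays accumulation window of the deployed bundle.
#'
#' @aliases DeviationReport-class
#' @exportClass DeviationReport
setClass("DeviationReport",
  representation(patientMedians = "numeric", nullMedians = "numeric",
                 tStatistic = "numeric", pValue = "numeric",
                 patientMAE = "numeric", gapYears = "numeric",
                 robustFit = "list", windowDays = "numeric"))
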