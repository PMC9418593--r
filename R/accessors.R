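#' Accessors for TapCohort
#'
#' @param x a \code{TapCohort}.
#' @return \code{tapStreams} returns the named list of timestamp vectors,
#'   \code{subjectData} the subject metadata \code{DataFrame},
#'   \code{nSubjects} the number of subjects.
#' @name TapCohort-accessors
#' @aliases tapStreams subjectData nSubjects
NULL

#' @rdname TapCohort-accessors
setMethod("tapStreams", "TapCohort", function(x) x@streams)

#' @rdname TapCohort-accessors
setMethod("subjectData", "TapCohort", function(x) x@subjects)

#' @rdname TapCohort-accessors
setMethod("nSubjects", "TapCohort", function(x) length(x@streams))

#' Accessors for JIDGrid
#'
#' @param x a \code{JIDGrid}.
#' @return \code{jidMass} the probability-mass matrix (rows: ITI at k,
#'   columns: ITI at k+1); \code{gridCenters} the log10-ms cell centers.
#' @name JIDGrid-accessors
#' @aliases jidMass gridCenters
NULL

#' @rdname JIDGrid-accessors
setMethod("jidMass", "JIDGrid", function(x) x@mass)

#' @rdname JIDGrid-accessors
setMethod("gridCenters", "JIDGrid", function(x) x@gridCenters)

#' Accessors for NormativeModel
#'
#' @param x a \code{NormativeModel}.
#' @name NormativeModel-accessors
#' @aliases foldAssignment foldModels hyperParams featureNames windowDays
NULL

#' @rdname NormativeModel-accessors
setMethod("foldAssignment", "NormativeModel", function(x) x@foldAssignment)

#' @rdname NormativeModel-accessors
setMethod("foldModels", "NormativeModel", function(x) x@foldModels)

#' @rdname NormativeModel-accessors
setMethod("hyperParams", "NormativeModel", function(x) x@hyperparams)

#' @rdname NormativeModel-accessors
setMethod("featureNames", "NormativeModel", function(x) x@featureNames)

#' @rdname NormativeModel-accessors
setMethod("windowDays", "NormativeModel", function(x) x@windowDays)

setMethod("show", "TapCohort", function(object) {
  tab <- table(object@subjects$cohort_label)
  cat("TapCohort with", nSubjects(object), "subjects (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
  if (nSubjects(object)) {
    cat("  ages:", paste(round(range(object@subjects$age_years), 1),
                         collapse = "-"), "years\n")
    cat("  recording days: median",
        stats::median(object@subjects$recording_days), "\n")
    cat("  events: total", sum(lengths(object@streams)), "\n")
  }
})

setMethod("show", "JIDGrid", function(object) {
  n <- length(object@gridCenters)
  cat("JIDGrid:", n, "x", n, "grid, log10-ms centers in [",
      min(object@gridCenters), ",", max(object@gridCenters),
      "], bandwidth", object@bandwidth, "\n")
  cat("  based on", object@nPairs, "interval pairs; total mass",
      format(sum(object@mass), digits = 10), "\n")
})

setMethod("show", "NormativeModel", function(object) {
  cat("NormativeModel:", length(object@foldModels), "fold models,",
      length(object@foldAssignment), "training subjects\n")
  hp <- object@hyperparams
  cat("  gradient-boosted trees: depth", hp$max_depth, ",", hp$n_trees,
      "trees, eta", hp$learning_rate, "\n")
  cat("  features:", length(object@featureNames),
      "; accumulation window:", object@windowDays, "days\n")
})

setMethod("show", "AttributionMap", function(object) {
  cat("AttributionMap:", nrow(object@perSubject), "subjects x",
      ncol(object@perSubject), "features\n")
  cat("  mean base value:", round(mean(object@baseValue), 2), "years\n")
  cat("  population JID maps: mean positive",
      format(mean(object@positiveMap), digits = 3), ", mean negative",
      format(mean(object@negativeMap), digits = 3), "\n")
})

setMethod("show", "DeviationReport", function(object) {
  cat("DeviationReport (window", object@windowDays, "days)\n")
  cat("  patient median errors (", length(object@patientMedians),
      " models): mean ", round(mean(object@patientMedians), 2), " years\n",
      sep = "")
  cat("  age-matched null (", length(object@nullMedians),
      " iterations): mean ", round(mean(object@nullMedians), 2), " years\n",
      sep = "")
  cat("  behavioral age gap:", round(object@gapYears, 2), "years; t =",
      round(object@tStatistic, 2), ", p =",
      format(object@pValue, digits = 3), "\n")
  rf <- object@robustFit
  cat("  per-patient robust fit: slope", round(rf$slope, 3), ", R2",
      round(rf$r2, 3), ", t(", rf$df, ") = ", round(rf$t, 2), "\n", sep = "")
})
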