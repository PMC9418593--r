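#' Configuration for the end-to-end pipeline
#'
#' @param outDir run directory; created if needed.
#' @param generator a \code{\link{generatorConfig}} describing both cohorts
#'   (healthy plus patients with the configured acceleration).
#' @param windowDays accumulation window (days) for both training and
#'   patient features; a single value enforces the window discipline (a
#'   bundle only ever scores features built at its own window).
#' @param hyperparams a \code{\link{modelHyperparams}}.
#' @param nIter,toleranceYears bootstrap settings for the deviation stage.
#' @param seed master seed for fold construction, training and bootstrap.
#' @param writeCohortFiles write the cohort CSVs into the run directory.
#' @return a list of class \code{tapage_run_config}.
#' @export
runConfig <- function(outDir, generator = generatorConfig(),
                      windowDays = 90, hyperparams = modelHyperparams(),
                      nIter = 10000L, toleranceYears = 2, seed = 1L,
                      writeCohortFiles = FALSE) {
  stopifnot(length(windowDays) == 1, windowDays >= 1)
  structure(list(outDir = outDir, generator = generator,
                 windowDays = windowDays, hyperparams = hyperparams,
                 nIter = as.integer(nIter),
                 toleranceYears = toleranceYears, seed = as.integer(seed),
                 writeCohortFiles = writeCohortFiles),
            class = "tapage_run_config")
}

#' Run the full behavioral-age analysis
#'
#' Orchestrates simulate -> filter -> featurize -> train -> evaluate ->
#' attribute -> deviate, writing every artifact plus a human-readable
#' summary into the run directory. Deterministic given the config.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisibly, a list with the bundle, prediction tables, metrics,
#'   attribution aggregates and the \code{\linkS4class{DeviationReport}}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "tapage_run_config"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  cohort <- stage("simulate", generateCohort(config$generator))
  cohort <- stage("filter", applyInclusionFilter(cohort, minDays = 7L))
  if (config$writeCohortFiles)
    stage("write", writeCohort(cohort, file.path(config$outDir, "cohort")))

  labels <- subjectData(cohort)$cohort_label
  healthy <- new("TapCohort",
                 streams = tapStreams(cohort)[labels == "healthy"],
                 subjects = subjectData(cohort)[labels == "healthy", ])
  seH <- stage("featurize", featurizeCohort(healthy, config$windowDays))

  bundle <- stage("train",
                  trainNormative(seH, hyperparams = config$hyperparams,
                                 seed = config$seed))
  saveNormativeModel(bundle, file.path(config$outDir, "bundle"))

  oof <- stage("predict", predictOutOfFold(bundle, seH))
  metrics <- performanceMetrics(oof)
  utils::write.csv(oof, file.path(config$outDir, "healthy_oof.csv"),
                   row.names = FALSE)

  attr <- stage("attribute", attributeShap(bundle, seH, mode = "oof"))
  agg <- aggregatePopulation(attr)
  utils::write.csv(agg$positive,
                   file.path(config$outDir, "shap_positive_map.csv"),
                   row.names = FALSE)
  utils::write.csv(agg$negative,
                   file.path(config$outDir, "shap_negative_map.csv"),
                   row.names = FALSE)

  report <- NULL
  if (any(labels == "patient")) {
    patients <- new("TapCohort",
                    streams = tapStreams(cohort)[labels == "patient"],
                    subjects = subjectData(cohort)[labels == "patient", ])
    seP <- stage("featurize-patients",
                 featurizeCohort(patients, config$windowDays))
    report <- stage("deviate",
                    assessDeviation(bundle, seP, oof, nIter = config$nIter,
                                    toleranceYears = config$toleranceYears,
                                    seed = config$seed))
    jsonlite::write_json(
      list(patient_medians = report@patientMedians,
           null_median_mean = mean(report@nullMedians),
           gap_years = report@gapYears, t = report@tStatistic,
           p = report@pValue, patient_MAE = report@patientMAE,
           robust_fit = report@robustFit,
           window_days = report@windowDays),
      file.path(config$outDir, "deviation_report.json"),
      auto_unbox = TRUE, digits = NA)
  }

  summary <- c(
    sprintf("subjects: %d healthy, %d patient", sum(labels == "healthy"),
            sum(labels == "patient")),
    sprintf("window: %g days; seed: %d", config$windowDays, config$seed),
    sprintf("healthy out-of-fold: ME %.2f y, MAE %.2f y, R2 %.3f",
            metrics$ME, metrics$MAE, metrics$R2),
    if (!is.null(report)) sprintf(
      "behavioral age gap: %.2f y (t = %.2f, p = %.3g); patient MAE %.2f y",
      report@gapYears, report@tStatistic, report@pValue,
      report@patientMAE))
  writeLines(summary, file.path(config$outDir, "summary.txt"))
  cfg <- config
  cfg$hyperparams <- unclass(cfg$hyperparams)
  cfg$generator <- unclass(cfg$generator)
  jsonlite::write_json(cfg[setdiff(names(cfg), "outDir")],
                       file.path(config$outDir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  message(paste(summary, collapse = "\n"))
  invisible(list(bundle = bundle, healthy_oof = oof, metrics = metrics,
                 attribution = agg, deviation = report))
}
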