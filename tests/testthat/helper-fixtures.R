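## Shared fixtures, built once per test run and memoised.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

## A small but real cohort: 30 healthy subjects, short recordings.
smallConfig <- function(...) {
  args <- utils::modifyList(
    list(nSubjects = 30, daysRange = c(8L, 12L), sessionsPerDay = 8,
         tapsPerSession = 6, seed = 42L), list(...))
  do.call(generatorConfig, args)
}

smallCohort <- function() memo("smallCohort", generateCohort(smallConfig()))

smallFeatures <- function() memo("smallFeatures",
                                 featurizeCohort(smallCohort(),
                                                 windowDays = 12))

## Light hyperparameters for unit tests of the model plumbing (the printed
## defaults are exercised in the acceptance suite).
lightParams <- function() modelHyperparams(nTrees = 40L, maxDepth = 4L,
                                           learningRate = 0.1)

smallBundle <- function() memo("smallBundle",
  trainNormative(smallFeatures(), hyperparams = lightParams(), k = 5L,
                 seed = 7L))

## Deterministic toy prediction table.
toyTable <- function(pred, real, fold = 1L) {
  data.frame(subject_id = sprintf("P%02d", seq_along(pred)),
             chronological_age = real, predicted_age = pred,
             error = pred - real, fold = fold, cohort_label = "patient")
}
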