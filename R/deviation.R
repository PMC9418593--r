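#' Per-model median prediction errors of a patient cohort
#'
#' From an all-models prediction table (\code{\link{predictCohort}}),
#' returns the median signed error (predicted - real, years) each fold
#' model makes over the patients: one "typical error" per model.
#'
#' @param patientTable prediction table with one row per subject x model.
#' @return numeric vector, one median per fold model.
#' @export
patientErrors <- function(patientTable) {
  if (length(unique(patientTable$subject_id)) < 2)
    stop("need at least 2 patients")
  meds <- tapply(patientTable$error, patientTable$fold, stats::median)
  as.numeric(meds[order(as.integer(names(meds)))])
}

#' Bootstrap null distribution of age-matched healthy median errors
#'
#' Per iteration, each patient is matched to one healthy subject sampled
#' uniformly from those within \code{toleranceYears} of the patient's age
#' (without replacement within the iteration), and the median of the
#' matched subjects' out-of-fold errors is recorded. Patients are matched
#' in order of ascending candidate-pool size so a thin pool fails loudly
#' rather than silently biasing the match.
#'
#' @param healthyOof out-of-fold prediction table of the healthy cohort.
#' @param patientAges chronological ages of the patients (years).
#' @param nIter bootstrap iterations, default 10000.
#' @param toleranceYears age-matching half-width, default 2.
#' @param seed integer seed; the draw is deterministic given it.
#' @return numeric vector of \code{nIter} median errors.
#' @export
bootstrapNull <- function(healthyOof, patientAges, nIter = 10000L,
                          toleranceYears = 2, seed = 1L) {
  stopifnot(nrow(healthyOof) >= length(patientAges), length(patientAges) > 0)
  hAges <- healthyOof$chronological_age
  hErr <- healthyOof$error
  candidates <- lapply(patientAges, function(a)
    which(abs(hAges - a) <= toleranceYears))
  npool <- lengths(candidates)
  if (any(npool == 0))
    stop("no healthy subject within ", toleranceYears,
         " years of patient age(s) ",
         paste(round(patientAges[npool == 0], 1), collapse = ", "))
  ord <- order(npool)  # scarcest pools first
  nP <- length(patientAges)
  set.seed(seed)
  medians <- numeric(nIter)
  for (it in seq_len(nIter)) {
    taken <- integer(nP)
    for (j in seq_len(nP)) {
      pool <- setdiff(candidates[[ord[j]]], taken[seq_len(j - 1L)])
      if (!length(pool))
        stop("insufficient healthy pool for without-replacement matching ",
             "at patient age ", round(patientAges[ord[j]], 1))
      taken[j] <- pool[sample.int(length(pool), 1L)]
    }
    medians[it] <- stats::median(hErr[taken])
  }
  medians
}

#' Compare patient and null median-error distributions
#'
#' Two-sample t-test between the per-model patient medians and the
#' bootstrap null medians. Welch's unequal-variance form is the default;
#' the pooled-variance test is available via \code{varEqual = TRUE}.
#'
#' @param patientMedians numeric, one value per fold model.
#' @param nullMedians numeric, one value per bootstrap iteration.
#' @param varEqual use the pooled-variance t-test.
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
compareDistributions <- function(patientMedians, nullMedians,
                                 varEqual = FALSE) {
  stopifnot(length(patientMedians) > 1, length(nullMedians) > 1)
  if (stats::sd(patientMedians) == 0 && stats::sd(nullMedians) == 0)
    stop("zero variance in both samples; t-test undefined")
  tt <- stats::t.test(patientMedians, nullMedians, var.equal = varEqual)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Robust regression of predicted on real age
#'
#' Huber M-estimation (iteratively reweighted least squares, tuning
#' constant 1.345) of per-patient predicted age on chronological age. The
#' slope t-statistic is reported on n - 2 degrees of freedom; R2 is the
#' squared Pearson correlation, the same convention as
#' \code{\link{performanceMetrics}}.
#'
#' @param predictedAges per-patient predicted age (median over the fold
#'   models unless summarised otherwise).
#' @param realAges chronological ages.
#' @return list: \code{slope}, \code{intercept}, \code{r2}, \code{t},
#'   \code{p}, \code{df}.
#' @export
robustAgeRegression <- function(predictedAges, realAges) {
  stopifnot(length(predictedAges) == length(realAges))
  n <- length(realAges)
  if (n < 3) stop("need at least 3 patients")
  if (stats::sd(realAges) == 0) stop("constant real ages; slope undefined")
  fit <- MASS::rlm(predictedAges ~ realAges, psi = MASS::psi.huber,
                   k = 1.345, maxit = 100)
  sm <- summary(fit)
  tval <- sm$coefficients["realAges", "t value"]
  df <- n - 2L
  list(slope = unname(stats::coef(fit)["realAges"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r2 = stats::cor(predictedAges, realAges)^2,
       t = unname(tval), p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Quantify advanced behavioral age in a patient cohort
#'
#' Deploys the normative bundle on the patients (all fold models), gathers
#' the per-model median errors, builds the bootstrap age-matched healthy
#' null from out-of-fold predictions, tests the two distributions against
#' each other, and fits the per-patient robust regression of predicted on
#' real age. The headline \code{gapYears} is
#' mean(patient medians) - mean(null medians): the years of behavioral age
#' advance beyond what age-matched healthy subjects show.
#'
#' @param bundle a \code{\linkS4class{NormativeModel}}.
#' @param patientSE patient features built at the bundle's window.
#' @param healthyOof out-of-fold prediction table of the healthy training
#'   cohort (never in-fold, so the null is not optimistically biased).
#' @param nIter,toleranceYears,seed passed to \code{\link{bootstrapNull}}.
#' @param summarise per-patient predicted age summarised over the fold
#'   models by the median (default) or mean.
#' @return a \code{\linkS4class{DeviationReport}}.
#' @export
assessDeviation <- function(bundle, patientSE, healthyOof,
                            nIter = 10000L, toleranceYears = 2, seed = 1L,
                            summarise = c("median", "mean")) {
  summarise <- match.arg(summarise)
  tab <- predictCohort(bundle, patientSE)
  pm <- patientErrors(tab)
  ages <- SummarizedExperiment::colData(patientSE)$age_years
  nm <- bootstrapNull(healthyOof, ages, nIter = nIter,
                      toleranceYears = toleranceYears, seed = seed)
  cmp <- compareDistributions(pm, nm)
  sfun <- if (summarise == "median") stats::median else mean
  perPatient <- tapply(tab$predicted_age, tab$subject_id, sfun)
  ids <- SummarizedExperiment::colData(patientSE)$subject_id
  rf <- robustAgeRegression(as.numeric(perPatient[ids]), ages)
  new("DeviationReport", patientMedians = pm, nullMedians = nm,
      tStatistic = cmp$t, pValue = cmp$p,
      patientMAE = mean(abs(tab$error)),
      gapYears = mean(pm) - mean(nm), robustFit = rf,
      windowDays = windowDays(bundle))
}
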