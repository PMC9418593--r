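mkPatientTable <- function(errByModel, nPatients = 5, ages = NULL) {
  if (is.null(ages)) ages <- seq(30, 70, length.out = nPatients)
  do.call(rbind, lapply(seq_along(errByModel), function(f)
    data.frame(subject_id = sprintf("P%02d", seq_len(nPatients)),
               chronological_age = ages,
               predicted_age = ages + errByModel[f],
               error = errByModel[f], fold = f,
               cohort_label = "patient")))
}

test_that("patient medians are one per model and order-invariant", {
  tab <- mkPatientTable(rep(0, 10))
  expect_equal(patientErrors(tab), rep(0, 10))
  tab5 <- mkPatientTable(rep(5, 10))
  expect_equal(patientErrors(tab5), rep(5, 10))
  shuffled <- tab5[sample(nrow(tab5)), ]
  expect_equal(patientErrors(shuffled), patientErrors(tab5))
  expect_error(patientErrors(mkPatientTable(1, nPatients = 1)),
               "at least 2")
})

mkHealthyOof <- function(n = 200, seed = 1) {
  set.seed(seed)
  ages <- runif(n, 16, 86)
  data.frame(subject_id = sprintf("H%03d", seq_len(n)),
             chronological_age = ages,
             predicted_age = ages + rnorm(n, 0, 6),
             error = rnorm(n, 0, 6), fold = rep(1:10, length.out = n),
             cohort_label = "healthy")
}

test_that("bootstrap matches ages within tolerance by construction", {
  oof <- mkHealthyOof()
  patAges <- c(25, 40, 41, 60, 75)
  ## instrument: recompute matches for one iteration by reproducing the draw
  tol <- 2
  for (a in patAges)
    expect_true(any(abs(oof$chronological_age - a) <= tol))
  nm <- bootstrapNull(oof, patAges, nIter = 50, toleranceYears = tol,
                      seed = 5)
  expect_length(nm, 50)
  ## all medians must be achievable from errors of subjects within
  ## tolerance of some patient age
  eligible <- unique(unlist(lapply(patAges, function(a)
    which(abs(oof$chronological_age - a) <= tol))))
  expect_true(all(nm >= min(oof$error[eligible]) &
                  nm <= max(oof$error[eligible])))
  ## deterministic given seed
  expect_identical(nm, bootstrapNull(oof, patAges, nIter = 50,
                                     toleranceYears = tol, seed = 5))
})

test_that("bootstrap fails loudly when no age-match exists", {
  oof <- mkHealthyOof()
  expect_error(bootstrapNull(oof, c(40, 150), nIter = 10), "150")
  ## without-replacement exhaustion: more patients than pool members
  tiny <- oof[1:5, ]
  tiny$chronological_age <- c(40, 40.5, 41, 300, 301)
  expect_error(bootstrapNull(tiny, rep(40.5, 4), nIter = 5,
                             toleranceYears = 1),
               "insufficient")
})

test_that("two-sample comparison behaves at its limits", {
  set.seed(8)
  a <- rnorm(10, 0, 1); b <- rnorm(2000, 0, 1)
  same <- compareDistributions(a - mean(a), b - mean(b))
  expect_lt(abs(same$t), 1)
  expect_gt(same$p, 0.05)

  shifted <- compareDistributions(a - mean(a) + 10,
                                  (b - mean(b)) * 0.01)
  expect_gt(abs(shifted$t), 20)
  expect_lt(shifted$p, 1e-3)

  expect_error(compareDistributions(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("Welch t-test matches the textbook formula on a toy set", {
  x <- c(1, 2, 3, 4, 10)
  y <- c(0, 0, 1, 1, 0, 1)
  got <- compareDistributions(x, y)
  ## hand computation of Welch's statistic and df
  se2 <- var(x) / length(x) + var(y) / length(y)
  tHand <- (mean(x) - mean(y)) / sqrt(se2)
  dfHand <- se2^2 / ((var(x) / 5)^2 / 4 + (var(y) / 6)^2 / 5)
  expect_equal(got$t, tHand, tolerance = 1e-12)
  expect_equal(got$df, dfHand, tolerance = 1e-9)
  expect_equal(got$p, 2 * pt(-abs(tHand), dfHand), tolerance = 1e-12)
})

test_that("robust regression resists a gross outlier where OLS does not", {
  real <- seq(20, 77, length.out = 20)
  pred <- real
  pred[20] <- pred[20] - 60   # one gross outlier
  rf <- robustAgeRegression(pred, real)
  expect_lt(abs(rf$slope - 1), 0.05)
  ols <- coef(lm(pred ~ real))["real"]
  expect_gt(abs(ols - 1), abs(rf$slope - 1))
  expect_equal(rf$df, 18)

  perfect <- robustAgeRegression(real, real)
  expect_equal(perfect$slope, 1, tolerance = 1e-9)
  expect_equal(perfect$intercept, 0, tolerance = 1e-6)
  expect_equal(perfect$r2, 1)

  expect_error(robustAgeRegression(c(1, 2, 3), rep(50, 3)), "constant")
  expect_error(robustAgeRegression(c(1, 2), c(3, 4)), "at least 3")
})

test_that("degrees of freedom are n - 2, as reported for cohorts", {
  set.seed(2)
  real <- runif(41, 22, 83)
  pred <- 0.4 * real + 30 + rnorm(41, 0, 8)
  rf <- robustAgeRegression(pred, real)
  expect_equal(rf$df, 39)
})

test_that("assessDeviation assembles a coherent report", {
  pat <- generateCohort(smallConfig(nSubjects = 0, nPatients = 6,
                                    accelerationYears = 10, seed = 31L))
  seP <- featurizeCohort(pat, windowDays = 12)
  oof <- predictOutOfFold(smallBundle(), smallFeatures())
  rep <- assessDeviation(smallBundle(), seP, oof, nIter = 200,
                         toleranceYears = 6, seed = 3)
  expect_length(rep@patientMedians, 5)   # one per fold model
  expect_length(rep@nullMedians, 200)
  expect_equal(rep@gapYears,
               mean(rep@patientMedians) - mean(rep@nullMedians))
  expect_equal(rep@robustFit$df, 4)
  expect_equal(rep@windowDays, 12)
  ## determinism
  rep2 <- assessDeviation(smallBundle(), seP, oof, nIter = 200,
                          toleranceYears = 6, seed = 3)
  expect_equal(rep2@nullMedians, rep@nullMedians)
  expect_equal(rep2@tStatistic, rep@tStatistic)
})
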