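test_that("folds are balanced, age-stratified and deterministic", {
  set.seed(1)
  recs <- data.frame(subject_id = sprintf("S%03d", 1:100),
                     age_years = runif(100, 16, 86))
  f <- makeFolds(recs, k = 10, seed = 3)
  expect_true(all(table(f) == 10))
  expect_identical(f, makeFolds(recs, k = 10, seed = 3))
  expect_false(identical(f, makeFolds(recs, k = 10, seed = 4)))

  recs300 <- data.frame(subject_id = sprintf("S%03d", 1:300),
                        age_years = runif(300, 16, 86))
  f300 <- makeFolds(recs300, k = 10, seed = 5)
  foldMeans <- tapply(recs300$age_years, f300[recs300$subject_id], mean)
  expect_true(all(abs(foldMeans - mean(recs300$age_years)) < 3))

  expect_error(makeFolds(recs[1:5, ], k = 10), "more folds")
})

test_that("uneven cohorts get fold sizes within one of each other", {
  recs <- data.frame(subject_id = sprintf("S%03d", 1:47),
                     age_years = seq(20, 80, length.out = 47))
  sizes <- table(makeFolds(recs, k = 10, seed = 1))
  expect_lte(diff(range(sizes)), 1)
})

test_that("training is deterministic and out-of-fold hygiene holds", {
  b1 <- smallBundle()
  b2 <- trainNormative(smallFeatures(), hyperparams = lightParams(),
                       k = 5L, seed = 7L)
  se <- smallFeatures()
  p1 <- predictOutOfFold(b1, se)
  p2 <- predictOutOfFold(b2, se)
  expect_equal(p1$predicted_age, p2$predicted_age, tolerance = 1e-12)

  ## every subject predicted exactly once, by the model that skipped it
  expect_setequal(p1$subject_id, colnames(SummarizedExperiment::assay(se)))
  expect_equal(anyDuplicated(p1$subject_id), 0)
  expect_identical(unname(foldAssignment(b1)[p1$subject_id]),
                   p1$fold)
  expect_equal(p1$error, p1$predicted_age - p1$chronological_age)
})

test_that("NaN in features is a hard error naming subject and feature", {
  se <- smallFeatures()
  X <- SummarizedExperiment::assay(se)
  X["screen_size", 3] <- NA
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = X),
    colData = SummarizedExperiment::colData(se),
    metadata = S4Vectors::metadata(se))
  expect_error(trainNormative(se2, hyperparams = lightParams(), k = 5L),
               "screen_size")
})

test_that("a constant-age cohort predicts that age", {
  se <- smallFeatures()
  cd <- SummarizedExperiment::colData(se)
  cd$age_years <- 47
  seC <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = SummarizedExperiment::assay(se)),
    colData = cd, metadata = S4Vectors::metadata(se))
  b <- trainNormative(seC, hyperparams = lightParams(), k = 5L, seed = 1L)
  p <- predictOutOfFold(b, seC)
  expect_true(all(abs(p$predicted_age - 47) < 1))
})

test_that("predictCohort scores every subject with every fold model", {
  b <- smallBundle()
  se <- smallFeatures()
  tab <- predictCohort(b, se)
  expect_equal(nrow(tab), 5 * ncol(SummarizedExperiment::assay(se)))
  expect_equal(sort(unique(tab$fold)), 1:5)
  perSubject <- table(tab$subject_id)
  expect_true(all(perSubject == 5))
})

test_that("a window mismatch between features and bundle errors", {
  b <- smallBundle()
  se <- smallFeatures()
  S4Vectors::metadata(se)$window_days <- 90
  expect_error(predictCohort(b, se), "window mismatch")
})

test_that("the null-input prediction is a deterministic baseline", {
  b <- smallBundle()
  X0 <- matrix(0, 1, length(featureNames(b)),
               dimnames = list("null", featureNames(b)))
  d0 <- xgboost::xgb.DMatrix(X0)
  p <- replicate(3, predict(foldModels(b)[[1]], d0))
  expect_true(all(p == p[1]))
})

test_that("performance metrics follow their definitions", {
  t1 <- toyTable(c(50, 60), c(50, 60))
  m1 <- performanceMetrics(t1)
  expect_equal(c(m1$ME, m1$MAE, m1$R2), c(0, 0, 1))

  m2 <- performanceMetrics(toyTable(c(50, 60), c(48, 62)))
  expect_equal(m2$ME, 0)
  expect_equal(m2$MAE, 2)

  ## squared-correlation convention: perfectly anti-correlated data has
  ## R2 = 1 (the documented caveat), while the coefficient of
  ## determination is negative
  m3 <- performanceMetrics(toyTable(c(60, 40, 20), c(20, 40, 60)))
  expect_equal(m3$R2, 1)
  expect_lt(m3$R2_cod, 0)

  expect_warning(m4 <- performanceMetrics(toyTable(c(5, 5), c(4, 9))),
                 "undefined")
  expect_true(is.na(m4$R2))
})

test_that("bundles serialize and reload with identical predictions", {
  dir <- withr::local_tempdir()
  b <- smallBundle()
  saveNormativeModel(b, dir)
  b2 <- loadNormativeModel(dir)
  se <- smallFeatures()
  expect_equal(predictOutOfFold(b2, se)$predicted_age,
               predictOutOfFold(b, se)$predicted_age, tolerance = 1e-12)
  expect_identical(foldAssignment(b2), foldAssignment(b))
  expect_equal(windowDays(b2), windowDays(b))
})

test_that("predicted age rises with true age on synthetic data", {
  p <- predictOutOfFold(smallBundle(), smallFeatures())
  expect_gt(cor(p$predicted_age, p$chronological_age,
                method = "spearman"), 0)
})
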