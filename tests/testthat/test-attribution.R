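test_that("tree Shapley matches the exhaustive-coalition oracle", {
  ## random ensembles of depth-3 trees over 8 features, no feature
  ## repeated within a path (the regime where the path algorithm equals
  ## the exhaustive Shapley value of the cover-expectation game)
  p <- 8
  for (case in 1:4) {
    trees <- lapply(1:3, function(k)
      randomUniqueTree(depth = 3, p = p, seed = 100 * case + k))
    set.seed(case)
    xs <- matrix(rnorm(3 * p), 3, p)
    res <- tapage:::.Call_treeshap(trees, xs, 0.5)
    for (i in 1:3) {
      oracle <- bruteForceShap(trees, xs[i, ], p)
      expect_equal(unname(res$phi[i, ]), oracle, tolerance = 1e-10)
    }
    ## base value equals the coalition value of the empty set
    expect_equal(res$base_value[1],
                 ensembleValue(trees, xs[1, ], integer(0)) + 0.5,
                 tolerance = 1e-10)
    ## efficiency: attributions bridge base value and prediction exactly
    expect_equal(rowSums(res$phi), res$prediction - res$base_value,
                 tolerance = 1e-10)
  }
})

test_that("hand-built stumps show additivity, null player and symmetry", {
  ## two symmetric stumps on different features with identical geometry
  t1 <- stumpTree(1, 0, vYes = -2, vNo = 2)
  t2 <- stumpTree(2, 0, vYes = -2, vNo = 2)
  x <- c(-1, -1, 99)
  res <- tapage:::.Call_treeshap(list(t1, t2), cbind(-1, -1, 99), 0)
  phi <- res$phi[1, ]
  ## symmetry: equal contributions for symmetric features
  expect_equal(phi[1], phi[2], tolerance = 1e-12)
  ## null player: feature 3 is never split on
  expect_equal(phi[3], 0)
  ## additivity in exact arithmetic
  expect_equal(res$base_value[1] + sum(phi), res$prediction[1],
               tolerance = 1e-12)
  ## the stump's Shapley value is (one_fraction - zero_fraction) * leaf gap
  oracle <- bruteForceShap(list(t1, t2), x, 3)
  expect_equal(unname(phi), oracle, tolerance = 1e-12)
})

test_that("double-precision path agrees with xgboost predcontrib", {
  set.seed(22)
  n <- 80; p <- 10
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rowSums(X[, 1:4]) + rnorm(n, 0, 0.2)
  fit <- tinyXgbTrees(X, y, nrounds = 25, max_depth = 4)
  res <- tapage:::.Call_treeshap(fit$trees, X, fit$base)
  ref <- predict(fit$bst, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  expect_lt(max(abs(res$phi - ref[, 1:p])), 1e-3)
  expect_lt(max(abs(res$base_value - ref[, p + 1])), 1e-3)
  ## and with xgboost's own predictions, up to its single-precision store
  expect_lt(max(abs(res$prediction - predict(fit$bst,
                                             xgboost::xgb.DMatrix(X)))),
            1e-3)
})

test_that("attributions of the normative bundle are additive to 1e-6", {
  map <- attributeShap(smallBundle(), smallFeatures(), mode = "oof")
  resid <- map@baseValue + rowSums(map@perSubject) - map@prediction
  expect_lt(max(abs(resid)), 1e-6)
  ## attribution-side predictions match the booster's to float precision
  p <- predictOutOfFold(smallBundle(), smallFeatures())
  expect_lt(max(abs(map@prediction[p$subject_id] - p$predicted_age)), 1e-3)
})

test_that("a feature constant in training gets zero attribution", {
  map <- attributeShap(smallBundle(), smallFeatures(), mode = "oof")
  ## screen sizes vary but many far-corner JID cells are ~constant zero;
  ## cells never split on must carry exactly 0
  used <- colSums(map@perSubject != 0) > 0
  expect_gt(sum(!used), 0)
  expect_true(all(map@perSubject[, !used] == 0))
})

test_that("ensemble mode averages the fold models for external subjects", {
  pat <- generateCohort(smallConfig(nSubjects = 0, nPatients = 4,
                                    accelerationYears = 5, seed = 9L))
  seP <- featurizeCohort(pat, windowDays = 12)
  map <- attributeShap(smallBundle(), seP)   # auto -> ensemble
  expect_equal(nrow(map@perSubject), 4)
  resid <- map@baseValue + rowSums(map@perSubject) - map@prediction
  expect_lt(max(abs(resid)), 1e-6)
  tab <- predictCohort(smallBundle(), seP)
  meanPred <- tapply(tab$predicted_age, tab$subject_id, mean)
  expect_lt(max(abs(map@prediction - meanPred[rownames(map@perSubject)])),
            1e-3)
})

test_that("population aggregation separates signs and decomposes", {
  map <- attributeShap(smallBundle(), smallFeatures(), mode = "oof")
  agg <- aggregatePopulation(map)
  expect_true(all(agg$positive >= 0))
  expect_true(all(agg$negative <= 0))
  ## positive + negative = plain mean map
  jidIdx <- grep("^jid_k[0-9]", featureNames(smallBundle()))
  meanMap <- matrix(colMeans(map@perSubject)[jidIdx], 50, 50, byrow = TRUE)
  expect_equal(agg$positive + agg$negative, meanMap, tolerance = 1e-12)
  expect_identical(agg$covariates$feature,
                   c("gender_code", "jid_entropy",
                     "log10_median_daily_taps", "screen_size"))
})

test_that("a single-subject population aggregates to its own split", {
  se <- smallFeatures()
  se1 <- se[, 1]
  map <- attributeShap(smallBundle(), se1, mode = "ensemble")
  agg <- aggregatePopulation(map)
  jidIdx <- grep("^jid_k[0-9]", featureNames(smallBundle()))
  own <- map@perSubject[1, jidIdx]
  expect_equal(agg$positive, matrix(pmax(own, 0), 50, 50, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(agg$negative, matrix(pmin(own, 0), 50, 50, byrow = TRUE),
               tolerance = 1e-12)
})
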