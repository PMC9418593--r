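#' Hyperparameters of the normative age model
#'
#' Defaults are the fixed configuration of the gradient-boosted tree
#' regression: maximum depth 9, 567 trees, learning rate 1e-2, minimum
#' child weight 8, L1 alpha 1e-3, column and row subsampling 1.0,
#' squared-error objective. These are frozen; re-tuning is out of scope.
#' \code{treeMethod}/\code{maxBin} select the histogram split-finding
#' algorithm and its resolution -- an algorithmic approximation, not a
#' model hyperparameter -- chosen so a 10-fold bundle trains in minutes on
#' one core.
#'
#' @param maxDepth,nTrees,learningRate,minChildWeight,l1Alpha,colSubsample,rowSubsample
#'   boosted-tree hyperparameters.
#' @param treeMethod xgboost tree construction algorithm.
#' @param maxBin histogram resolution for \code{treeMethod = "hist"}.
#' @return a list of class \code{tapage_hyperparams}.
#' @export
modelHyperparams <- function(maxDepth = 9L, nTrees = 567L,
                             learningRate = 1e-2, minChildWeight = 8,
                             l1Alpha = 1e-3, colSubsample = 1.0,
                             rowSubsample = 1.0, treeMethod = "hist",
                             maxBin = 32L) {
  structure(list(max_depth = as.integer(maxDepth),
                 n_trees = as.integer(nTrees),
                 learning_rate = learningRate,
                 min_child_weight = minChildWeight, l1_alpha = l1Alpha,
                 col_subsample = colSubsample, row_subsample = rowSubsample,
                 objective = "reg:squarederror",
                 tree_method = treeMethod, max_bin = as.integer(maxBin)),
            class = "tapage_hyperparams")
}

#' Age-stratified cross-validation folds
#'
#' Subjects are sorted by age and dealt into folds block-wise: within each
#' consecutive block of k subjects a random permutation of the fold labels
#' is assigned, so folds are balanced in size (within 1) and matched in age
#' distribution. Deterministic given the seed.
#'
#' @param records subject metadata (data.frame or DataFrame) with
#'   \code{subject_id} and \code{age_years}.
#' @param k number of folds, default 10.
#' @param seed integer seed.
#' @return named integer vector: subject_id -> fold index in 1..k.
#' @export
makeFolds <- function(records, k = 10L, seed = 1L) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (k > n) stop("more folds (", k, ") than subjects (", n, ")")
  set.seed(seed)
  ord <- order(records$age_years, stats::runif(n))  # random tie-break
  fold <- integer(n)
  for (start in seq(1L, n, by = k)) {
    block <- ord[start:min(start + k - 1L, n)]
    fold[block] <- sample(k)[seq_along(block)]
  }
  names(fold) <- records$subject_id
  fold
}

.xgbParams <- function(hp) {
  list(max_depth = hp$max_depth, eta = hp$learning_rate,
       min_child_weight = hp$min_child_weight, alpha = hp$l1_alpha,
       colsample_bytree = hp$col_subsample, subsample = hp$row_subsample,
       objective = hp$objective, tree_method = hp$tree_method,
       max_bin = hp$max_bin, nthread = 1)
}

.checkFeatureMatrix <- function(X) {
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("NaN/NA in features: subject ", colnames(X)[bad["col"]],
         ", feature ", rownames(X)[bad["row"]])
  }
}

#' Train the cross-validated normative age model
#'
#' Fits one gradient-boosted tree ensemble per fold, each trained on all
#' subjects outside that fold with chronological age as the target.
#' Training is single-threaded and seeded, so refitting with the same
#' inputs reproduces the bundle exactly.
#'
#' @param se a features \code{SummarizedExperiment} from
#'   \code{\link{featurizeCohort}} (healthy subjects).
#' @param folds fold assignment from \code{\link{makeFolds}}; built
#'   internally when NULL.
#' @param hyperparams a \code{\link{modelHyperparams}} list.
#' @param k folds when \code{folds} is NULL.
#' @param seed integer seed.
#' @return a \code{\linkS4class{NormativeModel}}.
#' @export
trainNormative <- function(se, folds = NULL,
                           hyperparams = modelHyperparams(), k = 10L,
                           seed = 1L) {
  X <- SummarizedExperiment::assay(se, "features")
  .checkFeatureMatrix(X)
  cd <- SummarizedExperiment::colData(se)
  if (is.null(folds)) folds <- makeFolds(cd, k = k, seed = seed)
  stopifnot(setequal(names(folds), colnames(X)))
  folds <- folds[colnames(X)]
  age <- cd$age_years
  nf <- max(folds)
  models <- vector("list", nf)
  for (f in seq_len(nf)) {
    tr <- folds != f
    dtrain <- xgboost::xgb.DMatrix(t(X[, tr, drop = FALSE]),
                                   label = age[tr])
    set.seed(seed + f)
    models[[f]] <- xgboost::xgb.train(params = .xgbParams(hyperparams),
                                      data = dtrain,
                                      nrounds = hyperparams$n_trees,
                                      verbose = 0)
  }
  new("NormativeModel", foldModels = models,
      foldAssignment = folds, hyperparams = unclass(hyperparams),
      featureNames = rownames(X),
      windowDays = S4Vectors::metadata(se)$window_days,
      seed = as.integer(seed))
}

.alignFeatures <- function(bundle, se, checkWindow = TRUE) {
  X <- SummarizedExperiment::assay(se, "features")
  if (!identical(rownames(X), featureNames(bundle)))
    stop("feature ordering does not match the bundle")
  if (checkWindow) {
    w <- S4Vectors::metadata(se)$window_days
    if (!is.null(w) && !isTRUE(all.equal(w, windowDays(bundle))))
      stop("accumulation window mismatch: features use ", w,
           " days, bundle was trained at ", windowDays(bundle))
  }
  X
}

#' Out-of-fold predictions for the training cohort
#'
#' Each subject is predicted only by the fold model that never saw it.
#'
#' @param bundle a \code{\linkS4class{NormativeModel}}.
#' @param se the features of the training cohort.
#' @return a prediction table: \code{subject_id}, \code{chronological_age},
#'   \code{predicted_age}, \code{error} (predicted - real, positive means
#'   "older" behavior), \code{fold}, \code{cohort_label}.
#' @export
predictOutOfFold <- function(bundle, se) {
  X <- .alignFeatures(bundle, se)
  folds <- foldAssignment(bundle)
  unknown <- setdiff(colnames(X), names(folds))
  if (length(unknown))
    stop("subject(s) without fold assignment: ",
         paste(unknown, collapse = ", "))
  cd <- SummarizedExperiment::colData(se)
  pred <- numeric(ncol(X))
  for (f in seq_along(foldModels(bundle))) {
    idx <- which(folds[colnames(X)] == f)
    if (!length(idx)) next
    pred[idx] <- stats::predict(foldModels(bundle)[[f]],
                                xgboost::xgb.DMatrix(t(X[, idx, drop = FALSE])))
  }
  data.frame(subject_id = colnames(X), chronological_age = cd$age_years,
             predicted_age = pred, error = pred - cd$age_years,
             fold = unname(folds[colnames(X)]),
             cohort_label = cd$cohort_label, row.names = NULL)
}

#' Predictions for an external cohort by all fold models
#'
#' Every subject is scored by each of the fold models, giving (number of
#' models) rows per subject; the \code{fold} column indexes the model. The
#' features must use the bundle's accumulation window.
#'
#' @inheritParams predictOutOfFold
#' @param se features of the cohort to score (e.g. patients).
#' @return a prediction table as in \code{\link{predictOutOfFold}}.
#' @export
predictCohort <- function(bundle, se) {
  X <- .alignFeatures(bundle, se)
  cd <- SummarizedExperiment::colData(se)
  dm <- xgboost::xgb.DMatrix(t(X))
  out <- lapply(seq_along(foldModels(bundle)), function(f) {
    p <- stats::predict(foldModels(bundle)[[f]], dm)
    data.frame(subject_id = colnames(X), chronological_age = cd$age_years,
               predicted_age = p, error = p - cd$age_years, fold = f,
               cohort_label = cd$cohort_label, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Prediction performance metrics
#'
#' ME = mean(predicted - real); MAE = mean absolute error; R2 = squared
#' Pearson correlation between predicted and real age (the convention of
#' the normative-age literature; note it is 1 for any perfectly linear
#' relation, including an anti-correlated one). The coefficient of
#' determination is also returned as \code{R2_cod}.
#'
#' @param table a prediction table.
#' @return list with \code{ME}, \code{MAE}, \code{R2}, \code{R2_cod}, and
#'   \code{n}.
#' @export
performanceMetrics <- function(table) {
  stopifnot(nrow(table) >= 2)
  me <- mean(table$error)
  mae <- mean(abs(table$error))
  if (stats::sd(table$predicted_age) == 0 ||
      stats::sd(table$chronological_age) == 0) {
    warning("constant predictions or ages; R2 undefined")
    r2 <- NA_real_
  } else {
    r2 <- stats::cor(table$predicted_age, table$chronological_age)^2
  }
  ss <- sum((table$chronological_age - mean(table$chronological_age))^2)
  list(ME = me, MAE = mae, R2 = r2,
       R2_cod = 1 - sum(table$error^2) / ss, n = nrow(table))
}

#' Sensitivity of model error to recording duration
#'
#' Re-featurizes the training cohort from streams truncated to each test
#' duration, scores the truncated features out-of-fold with a bundle
#' trained on the full window, and reports the MAE per duration with a
#' bootstrap 95% confidence band over subjects. Subjects falling below
#' \code{minDays} at a truncation are dropped (count reported).
#'
#' @param bundle bundle trained on full-window features.
#' @param cohort the training \code{\linkS4class{TapCohort}}.
#' @param testDays durations (days) to evaluate, e.g. c(5, 10, 30, 60, 90).
#' @param minDays inclusion threshold applied after truncation.
#' @param nBoot bootstrap resamples for the confidence band.
#' @param seed seed for the bootstrap.
#' @return data.frame with \code{days}, \code{MAE}, \code{ME}, \code{lo},
#'   \code{hi}, \code{n_subjects}.
#' @export
durationSensitivity <- function(bundle, cohort, testDays = c(5, 10, 30, 60,
                                                             90, 180),
                                minDays = 1L, nBoot = 500L, seed = 1L) {
  stopifnot(is(cohort, "TapCohort"))
  res <- vector("list", length(testDays))
  for (j in seq_along(testDays)) {
    d <- testDays[j]
    trunc <- new("TapCohort",
                 streams = lapply(tapStreams(cohort), accumulateWindow, d),
                 subjects = subjectData(cohort))
    days <- vapply(tapStreams(trunc),
                   function(ts) length(unique(ts %/% MS_PER_DAY)),
                   integer(1))
    if (any(days < minDays)) {
      message(sum(days < minDays), " subject(s) below ", minDays,
              " days at truncation ", d, "; dropped")
      trunc <- new("TapCohort",
                   streams = tapStreams(trunc)[days >= minDays],
                   subjects = subjectData(trunc)[days >= minDays, ,
                                                 drop = FALSE])
    }
    seT <- featurizeCohort(trunc, windowDays = d)
    S4Vectors::metadata(seT)$window_days <- windowDays(bundle)  # deliberate
    tab <- predictOutOfFold(bundle, seT)
    set.seed(seed + j)
    boots <- replicate(nBoot, {
      idx <- sample.int(nrow(tab), replace = TRUE)
      mean(abs(tab$error[idx]))
    })
    res[[j]] <- data.frame(days = d, MAE = mean(abs(tab$error)),
                           ME = mean(tab$error),
                           lo = stats::quantile(boots, 0.025, names = FALSE),
                           hi = stats::quantile(boots, 0.975, names = FALSE),
                           n_subjects = nrow(tab))
  }
  do.call(rbind, res)
}

#' Save / load a normative model bundle
#'
#' The bundle is persisted as a directory: one JSON-serialised booster per
#' fold plus a manifest (hyperparameters, feature ordering, window, seed,
#' fold map). Reloading reproduces predictions exactly.
#'
#' @param bundle a \code{\linkS4class{NormativeModel}}.
#' @param dir bundle directory.
#' @return \code{loadNormativeModel} returns the restored bundle.
#' @export
saveNormativeModel <- function(bundle, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create ", dir)
  for (f in seq_along(foldModels(bundle)))
    xgboost::xgb.save(foldModels(bundle)[[f]],
                      file.path(dir, sprintf("fold_%02d.json", f)))
  manifest <- list(hyperparams = hyperParams(bundle),
                   feature_names = featureNames(bundle),
                   window_days = windowDays(bundle), seed = bundle@seed,
                   fold_assignment = as.list(foldAssignment(bundle)),
                   n_folds = length(foldModels(bundle)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveNormativeModel
#' @param dir bundle directory written by \code{saveNormativeModel}.
#' @export
loadNormativeModel <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  nf <- manifest$n_folds
  models <- lapply(seq_len(nf), function(f)
    xgboost::xgb.load(file.path(dir, sprintf("fold_%02d.json", f))))
  fa <- unlist(manifest$fold_assignment)
  new("NormativeModel", foldModels = models,
      foldAssignment = stats::setNames(as.integer(fa), names(fa)),
      hyperparams = manifest$hyperparams,
      featureNames = unlist(manifest$feature_names),
      windowDays = manifest$window_days, seed = as.integer(manifest$seed))
}
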