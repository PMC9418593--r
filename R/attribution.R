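## Flatten the JSON tree dump of one booster into the arrays the compiled
## Shapley routine consumes. Feature names are mapped to 0-based indices in
## the bundle's feature ordering.
.parseTrees <- function(model, featNames) {
  dump <- xgboost::xgb.dump(model, with_stats = TRUE, dump_format = "json")
  trees <- jsonlite::fromJSON(paste(dump, collapse = "\n"),
                              simplifyVector = FALSE)
  lapply(trees, function(root) {
    nodes <- list()
    walk <- function(nd) {
      nodes[[length(nodes) + 1L]] <<- nd
      if (!is.null(nd$children)) for (ch in nd$children) walk(ch)
    }
    walk(root)
    id <- vapply(nodes, function(nd) nd$nodeid, numeric(1))
    isLeaf <- vapply(nodes, function(nd) is.null(nd$split), logical(1))
    feat <- rep(-1L, length(nodes))
    thr <- rep(NA_real_, length(nodes))
    yes <- no <- rep(-1L, length(nodes))
    val <- rep(0, length(nodes))
    cov <- vapply(nodes, function(nd) as.numeric(nd$cover), numeric(1))
    for (i in seq_along(nodes)) {
      nd <- nodes[[i]]
      if (isLeaf[i]) {
        val[i] <- as.numeric(nd$leaf)
      } else {
        f <- match(nd$split, featNames)
        if (is.na(f)) f <- as.integer(sub("^f", "", nd$split)) + 1L
        feat[i] <- f - 1L
        thr[i] <- as.numeric(nd$split_condition)
        yes[i] <- match(nd$yes, id) - 1L
        no[i] <- match(nd$no, id) - 1L
      }
    }
    list(feature = as.integer(feat), threshold = as.numeric(thr),
         yes = as.integer(yes), no = as.integer(no),
         value = as.numeric(val), cover = as.numeric(cov))
  })
}

.baseScore <- function(model) {
  cfg <- xgboost::xgb.config(model)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  as.numeric(cfg$learner$learner_model_param$base_score)
}

## Double-precision Shapley attributions of one booster for a feature
## matrix X (subjects x features). Returns phi, the tree-ensemble
## prediction recomputed in double precision, and the cover-weighted
## expected output (base value).
.shapOneModel <- function(model, X, featNames) {
  trees <- .parseTrees(model, featNames)
  .Call_treeshap(trees, X, .baseScore(model))
}

#' Shapley attributions of the normative model's predictions
#'
#' Computes exact per-feature Shapley values (years) for each subject by
#' the polynomial-time tree algorithm, in double precision, with the
#' cover-weighted conditional expectations the trees were trained with.
#' For subjects of the training cohort (\code{mode = "oof"}) each subject
#' is attributed by the fold model that never saw it; for external cohorts
#' (\code{mode = "ensemble"}) attributions are averaged over all fold
#' models. The defining additivity property -- base value plus the sum of
#' attributions equals the prediction -- holds to 1e-6 per subject.
#'
#' @param bundle a \code{\linkS4class{NormativeModel}}.
#' @param se a features \code{SummarizedExperiment}.
#' @param mode \code{"auto"} picks \code{"oof"} when every subject has a
#'   fold assignment, \code{"ensemble"} otherwise.
#' @return an \code{\linkS4class{AttributionMap}}.
#' @export
attributeShap <- function(bundle, se, mode = c("auto", "oof", "ensemble")) {
  mode <- match.arg(mode)
  X <- t(.alignFeatures(bundle, se, checkWindow = FALSE))
  folds <- foldAssignment(bundle)
  if (mode == "auto")
    mode <- if (all(rownames(X) %in% names(folds))) "oof" else "ensemble"
  fn <- featureNames(bundle)
  n <- nrow(X)
  phi <- matrix(0, n, ncol(X), dimnames = dimnames(X))
  base <- pred <- stats::setNames(numeric(n), rownames(X))
  if (mode == "oof") {
    missing <- setdiff(rownames(X), names(folds))
    if (length(missing))
      stop("no fold assignment for: ", paste(missing, collapse = ", "))
    for (f in seq_along(foldModels(bundle))) {
      idx <- which(folds[rownames(X)] == f)
      if (!length(idx)) next
      r <- .shapOneModel(foldModels(bundle)[[f]], X[idx, , drop = FALSE], fn)
      phi[idx, ] <- r$phi
      base[idx] <- r$base_value
      pred[idx] <- r$prediction
    }
  } else {
    for (f in seq_along(foldModels(bundle))) {
      r <- .shapOneModel(foldModels(bundle)[[f]], X, fn)
      phi <- phi + r$phi
      base <- base + r$base_value
      pred <- pred + r$prediction
    }
    k <- length(foldModels(bundle))
    phi <- phi / k; base <- base / k; pred <- pred / k
  }
  agg <- .aggregateMaps(phi, fn)
  new("AttributionMap", perSubject = phi, baseValue = base,
      prediction = pred, positiveMap = agg$positive,
      negativeMap = agg$negative, covariateSummary = agg$covariates)
}

.aggregateMaps <- function(phi, featNames) {
  jidIdx <- grep("^jid_k[0-9]", featNames)
  nBins <- as.integer(sqrt(length(jidIdx)))
  meanPos <- colMeans(pmax(phi, 0))
  meanNeg <- colMeans(pmin(phi, 0))
  ## invert the row-major (ITI_k major) vectorisation back to 50 x 50
  pos <- matrix(meanPos[jidIdx], nBins, nBins, byrow = TRUE)
  neg <- matrix(meanNeg[jidIdx], nBins, nBins, byrow = TRUE)
  covIdx <- setdiff(seq_along(featNames), jidIdx)
  list(positive = pos, negative = neg,
       covariates = data.frame(feature = featNames[covIdx],
                               mean_positive = meanPos[covIdx],
                               mean_negative = meanNeg[covIdx],
                               mean_abs = colMeans(abs(phi))[covIdx],
                               row.names = NULL))
}

#' Population aggregation of an attribution map
#'
#' Per JID cell, the mean over subjects of the positive part and of the
#' negative part of the attribution (computed per subject before
#' averaging, so the red/blue separation is not cancelled out); the plain
#' mean attribution map is their sum. Covariates are summarised separately.
#'
#' @param map an \code{\linkS4class{AttributionMap}}.
#' @return list with \code{positive} and \code{negative} 50 x 50 maps,
#'   \code{mean} (their sum) and \code{covariates}.
#' @export
aggregatePopulation <- function(map) {
  stopifnot(is(map, "AttributionMap"))
  list(positive = map@positiveMap, negative = map@negativeMap,
       mean = map@positiveMap + map@negativeMap,
       covariates = map@covariateSummary)
}
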