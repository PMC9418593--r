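## Raw (unnormalised) Gaussian kernel density summed over pairs, evaluated
## at the grid centers. Separable kernel: D = Kx %*% t(Ky) with
## Kx[i, p] = dnorm(cx[i] - log10(iti_k[p]), sd = bw).
.jidDensityRaw <- function(log10k, log10k1, centers, bandwidth) {
  Kx <- stats::dnorm(outer(centers, log10k, "-"), sd = bandwidth)
  Ky <- stats::dnorm(outer(centers, log10k1, "-"), sd = bandwidth)
  Kx %*% t(Ky)
}

#' Compute the joint interval distribution of consecutive ITI pairs
#'
#' Maps each interval pair to (log10 ITI_k, log10 ITI_k+1) and estimates the
#' joint density with an isotropic 2D Gaussian kernel (bandwidth in log10
#' units, default 0.1), evaluated at \code{nBins} equally spaced cell
#' centers per axis spanning log10-ms \code{rangeLog10} (default [0.5, 5],
#' i.e. ~3 ms to ~28 h). Cell values are renormalised to a probability mass
#' summing to 1; pairs outside the range still contribute kernel mass to
#' in-grid cells, and mass falling off the grid is discarded by the
#' renormalisation.
#'
#' @param pairs an ITI pair set from \code{\link{extractItiPairs}}, or a
#'   2-column matrix of (ITI_k, ITI_k+1) in ms.
#' @param bandwidth Gaussian kernel bandwidth in log10-ms units.
#' @param nBins number of cells per axis.
#' @param rangeLog10 log10-ms span of the cell centers.
#' @return a \code{\linkS4class{JIDGrid}}; rows index ITI at k, columns ITI
#'   at k+1.
#' @examples
#' p <- matrix(rep(1000, 20), ncol = 2)
#' computeJID(p)
#' @export
computeJID <- function(pairs, bandwidth = 0.1, nBins = 50L,
                       rangeLog10 = c(0.5, 5.0)) {
  if (is.list(pairs) && !is.null(pairs$pairs)) pairs <- pairs$pairs
  pairs <- as.matrix(pairs)
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (nrow(pairs) == 0L)
    stop("no interval pairs; exclude this subject upstream")
  if (any(pairs <= 0)) stop("all ITIs must be > 0")
  centers <- seq(rangeLog10[1], rangeLog10[2], length.out = nBins)
  dens <- .jidDensityRaw(log10(pairs[, 1]), log10(pairs[, 2]),
                         centers, bandwidth)
  new("JIDGrid", mass = dens / sum(dens), gridCenters = centers,
      bandwidth = bandwidth, nPairs = nrow(pairs))
}

#' Shannon entropy of a JID
#'
#' \eqn{-\sum p \log_2 p} over the 2500 cells, with 0 log 0 taken as 0.
#' Bounded by 0 (point mass) and log2(number of cells) (uniform).
#'
#' @param grid a \code{\linkS4class{JIDGrid}} (normalised by construction).
#' @return entropy in bits.
#' @export
jidEntropy <- function(grid) {
  stopifnot(is(grid, "JIDGrid"))
  p <- jidMass(grid)
  if (abs(sum(p) - 1) > 1e-9) stop("JID mass is not normalised")
  p <- p[p > 0]
  -sum(p * log2(p)) + 0   # + 0 avoids IEEE negative zero
}

#' Assemble the model feature vector for one subject
#'
#' Concatenates, in fixed order: the 2500 JID cells (row-major, ITI at k
#' major and ITI at k+1 minor), then \code{gender_code},
#' \code{jid_entropy} (bits), \code{log10_median_daily_taps} (log10 of the
#' median per-day interaction count over days with data) and
#' \code{screen_size}. Missing covariates are an error; nothing is imputed.
#'
#' @param grid a \code{\linkS4class{JIDGrid}} for the subject.
#' @param record one-row subject metadata (data.frame or DataFrame) with
#'   \code{gender_code} and \code{screen_size}.
#' @param tapsPerDay per-day interaction counts over the same accumulation
#'   window the grid used.
#' @return named numeric vector of length \code{nBins^2 + 4}.
#' @export
assembleFeatures <- function(grid, record, tapsPerDay) {
  stopifnot(is(grid, "JIDGrid"))
  record <- as.data.frame(record)
  for (f in c("gender_code", "screen_size"))
    if (is.null(record[[f]]) || is.na(record[[f]]))
      stop("missing covariate '", f, "' for subject ",
           record$subject_id %||% "?")
  if (!length(tapsPerDay) || any(is.na(tapsPerDay)))
    stop("tapsPerDay missing for subject ", record$subject_id %||% "?")
  jid <- as.vector(t(jidMass(grid)))   # row-major: ITI_k major
  names(jid) <- jidFeatureNames(length(gridCenters(grid)))
  c(jid,
    gender_code = as.numeric(record$gender_code),
    jid_entropy = jidEntropy(grid),
    log10_median_daily_taps = log10(stats::median(as.numeric(tapsPerDay))),
    screen_size = as.numeric(record$screen_size))
}

jidFeatureNames <- function(nBins = 50L) {
  sprintf("jid_k%02d_k1%02d", rep(seq_len(nBins), each = nBins),
          rep(seq_len(nBins), nBins))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Featurize a whole cohort into a SummarizedExperiment
#'
#' Runs, per subject: window accumulation, ITI pair extraction, JID
#' estimation and feature assembly. Subjects left with zero within-day
#' interval pairs are dropped with a message. The result is a
#' \code{SummarizedExperiment} with one \code{features} assay
#' (features x subjects), subject metadata (including chronological age,
#' the regression target) as \code{colData}, and the accumulation window
#' and KDE settings in \code{metadata()}.
#'
#' @param cohort a \code{\linkS4class{TapCohort}}.
#' @param windowDays accumulation window in days (e.g. 90 or 180).
#' @param bandwidth,nBins,rangeLog10 passed to \code{\link{computeJID}}.
#' @return a \code{SummarizedExperiment}.
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata
featurizeCohort <- function(cohort, windowDays, bandwidth = 0.1,
                            nBins = 50L, rangeLog10 = c(0.5, 5.0)) {
  stopifnot(is(cohort, "TapCohort"))
  meta <- as.data.frame(subjectData(cohort))
  feats <- vector("list", nSubjects(cohort))
  ok <- logical(nSubjects(cohort))
  for (i in seq_len(nSubjects(cohort))) {
    ts <- accumulateWindow(tapStreams(cohort)[[i]], windowDays)
    ps <- suppressWarnings(extractItiPairs(ts, meta$subject_id[i]))
    if (nrow(ps$pairs) == 0L) next
    grid <- computeJID(ps$pairs, bandwidth, nBins, rangeLog10)
    feats[[i]] <- assembleFeatures(grid, meta[i, , drop = FALSE],
                                   ps$taps_per_day)
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("no subject produced any interval pairs")
  if (any(!ok))
    message(sum(!ok), " subject(s) dropped: no within-day interval pairs")
  mat <- do.call(cbind, feats[ok])
  colnames(mat) <- meta$subject_id[ok]
  SummarizedExperiment(
    assays = list(features = mat),
    colData = DataFrame(meta[ok, , drop = FALSE],
                        row.names = meta$subject_id[ok]),
    metadata = list(window_days = windowDays, bandwidth = bandwidth,
                    n_bins = nBins, range_log10 = rangeLog10))
}
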