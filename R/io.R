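#' Write a cohort to disk
#'
#' Writes one timestamps CSV per subject (columns \code{subject_id},
#' \code{timestamp_ms}) plus a cohort metadata CSV, the formats
#' \code{\link{readCohort}} reads back losslessly.
#'
#' @param cohort a \code{\linkS4class{TapCohort}}.
#' @param dir output directory, created if needed.
#' @return invisibly, a data.frame manifest of the files written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "TapCohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  meta <- as.data.frame(subjectData(cohort))
  metaPath <- file.path(dir, "cohort_metadata.csv")
  utils::write.csv(meta[, c("subject_id", "age_years", "gender_code",
                            "screen_size", "cohort_label")],
                   metaPath, row.names = FALSE, quote = FALSE)
  files <- character(nSubjects(cohort))
  for (i in seq_len(nSubjects(cohort))) {
    id <- meta$subject_id[i]
    files[i] <- file.path(dir, paste0("taps_", id, ".csv"))
    utils::write.csv(
      data.frame(subject_id = id,
                 timestamp_ms = format(tapStreams(cohort)[[i]],
                                       scientific = FALSE, trim = TRUE)),
      files[i], row.names = FALSE, quote = FALSE)
  }
  invisible(data.frame(subject_id = meta$subject_id, file = files,
                       stringsAsFactors = FALSE))
}

#' Read a cohort from disk
#'
#' Reads the per-subject timestamp CSVs and metadata table written by
#' \code{\link{writeCohort}}. Timestamps are sorted if out of order (with a
#' warning) and exact duplicate timestamps are dropped (with a warning
#' giving the count); a stream without a metadata row is a hard error. A
#' JSON sidecar recording these filter decisions is written next to the
#' data.
#'
#' @param dir directory containing \code{cohort_metadata.csv} and
#'   \code{taps_<id>.csv} files.
#' @return a \code{\linkS4class{TapCohort}}.
#' @export
readCohort <- function(dir) {
  metaPath <- file.path(dir, "cohort_metadata.csv")
  if (!file.exists(metaPath)) stop("no cohort_metadata.csv in ", dir)
  meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
  tapFiles <- list.files(dir, pattern = "^taps_.*\\.csv$", full.names = TRUE)
  ids <- sub("^taps_(.*)\\.csv$", "\\1", basename(tapFiles))
  orphan <- setdiff(ids, meta$subject_id)
  if (length(orphan))
    stop("timestamp file(s) without metadata row: ",
         paste(orphan, collapse = ", "))
  keep <- meta$subject_id %in% ids
  meta <- meta[keep, , drop = FALSE]
  streams <- vector("list", nrow(meta))
  names(streams) <- meta$subject_id
  log <- list()
  for (id in meta$subject_id) {
    ts <- utils::read.csv(file.path(dir, paste0("taps_", id, ".csv")),
                          colClasses = c(subject_id = "character",
                                         timestamp_ms = "numeric"))$timestamp_ms
    if (is.unsorted(ts)) {
      warning("non-monotone timestamps for ", id, "; sorted")
      ts <- sort(ts)
      log[[id]]$sorted <- TRUE
    }
    nd <- sum(duplicated(ts))
    if (nd > 0) {
      warning(nd, " duplicate timestamp(s) dropped for ", id)
      ts <- unique(ts)
      log[[id]]$duplicates_dropped <- nd
    }
    streams[[id]] <- ts
  }
  days <- vapply(streams,
                 function(ts) length(unique(ts %/% MS_PER_DAY)), integer(1))
  meta$recording_days <- days
  jsonlite::write_json(list(subjects_read = nrow(meta), filters = log),
                       file.path(dir, "read_log.json"), auto_unbox = TRUE)
  new("TapCohort", streams = streams, subjects = DataFrame(meta))
}

#' Truncate a stream to its first calendar days
#'
#' Keeps events from the first \code{maxDays} distinct calendar days of the
#' recording (the full stream if it is shorter). Used to accumulate
#' interactions over a bounded window, e.g. a maximum of 90 or 180 days.
#'
#' @param timestamps numeric vector of ms timestamps for one subject.
#' @param maxDays integer >= 1.
#' @return the truncated timestamp vector.
#' @export
accumulateWindow <- function(timestamps, maxDays) {
  stopifnot(maxDays >= 1)
  if (!length(timestamps)) return(timestamps)
  day <- timestamps %/% MS_PER_DAY
  keepDays <- unique(day)[seq_len(min(maxDays, length(unique(day))))]
  timestamps[day %in% keepDays]
}

#' Apply the minimum-recording-length inclusion filter
#'
#' Removes subjects with fewer than \code{minDays} distinct days with data
#' (the threshold is inclusive: exactly \code{minDays} days is kept). The
#' number of removals is reported via message.
#'
#' @param cohort a \code{\linkS4class{TapCohort}}.
#' @param minDays minimum distinct recording days, default 7.
#' @return the filtered \code{TapCohort}.
#' @export
applyInclusionFilter <- function(cohort, minDays = 7L) {
  stopifnot(is(cohort, "TapCohort"))
  days <- vapply(tapStreams(cohort),
                 function(ts) length(unique(ts %/% MS_PER_DAY)), integer(1))
  keep <- days >= minDays
  if (!any(keep)) stop("no subject has >= ", minDays,
                       " recording days; nothing to model")
  if (any(!keep))
    message(sum(!keep), " subject(s) removed by the ", minDays,
            "-day inclusion filter")
  new("TapCohort", streams = tapStreams(cohort)[keep],
      subjects = subjectData(cohort)[keep, , drop = FALSE])
}

#' Extract consecutive inter-touch interval pairs
#'
#' Computes inter-touch intervals (ITIs) between successive events and forms
#' consecutive pairs (ITI at k, ITI at k+1). Pairs are never formed across a
#' midnight day boundary: overnight gaps would otherwise dominate the slow
#' tail with artifactual mass. Duplicate timestamps (zero ITIs) are dropped
#' before pairing since log10(0) is undefined. An unbroken run of m
#' same-day events yields m - 2 pairs (m >= 3), otherwise none.
#'
#' @param timestamps numeric vector of ms timestamps for one subject.
#' @param subjectId optional id carried through for reporting.
#' @return a list with \code{subject_id}, \code{pairs} (n x 2 matrix of ms
#'   intervals), \code{n_days_used} and \code{taps_per_day} (named integer
#'   vector of per-day event counts over days with data).
#' @export
extractItiPairs <- function(timestamps, subjectId = NA_character_) {
  ts <- unique(sort(timestamps))
  day <- ts %/% MS_PER_DAY
  tapsPerDay <- table(day)
  if (length(ts) < 3L) {
    warning("fewer than 3 events; no interval pairs for ", subjectId)
    return(list(subject_id = subjectId,
                pairs = matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("iti_k", "iti_k1"))),
                n_days_used = length(tapsPerDay),
                taps_per_day = c(tapsPerDay)))
  }
  iti <- diff(ts)
  sameDay <- diff(day) == 0            # interval i stays within one day
  ok <- sameDay[-length(sameDay)] & sameDay[-1]   # both intervals of a pair
  pairs <- cbind(iti_k = iti[-length(iti)][ok], iti_k1 = iti[-1][ok])
  list(subject_id = subjectId, pairs = pairs,
       n_days_used = length(tapsPerDay), taps_per_day = c(tapsPerDay))
}
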