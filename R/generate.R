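MS_PER_DAY <- 86400000

#' Configuration for the synthetic tappigraphy generator
#'
#' Builds and validates the parameter list of \code{\link{generateCohort}}.
#' Inter-touch intervals (ITIs) are drawn from a mixture of lognormal
#' "regimes" -- fast typing-like bursts (~100 ms), medium (~1 s), slow
#' (~4 s) and gap (~30 s) intervals -- with first-order Markov persistence so
#' that consecutive intervals are serially dependent (the joint interval
#' distribution would factor into an outer product otherwise). Age shifts
#' the mixture-weight logits linearly: the default slopes make fast-interval
#' mass decline, and slow/gap mass rise, over the sampled 16-86 year span,
#' the direction reported for human smartphone use. All magnitudes are
#' invented generator plumbing; no published generative law for ITIs exists.
#'
#' @param nSubjects number of healthy subjects.
#' @param nPatients number of additional "patient" subjects, generated at
#'   effective age \code{age + accelerationYears} while their metadata keeps
#'   the chronological age.
#' @param ageRange sampled chronological age range in years.
#' @param daysRange recording duration range in days (durations sampled
#'   uniformly per subject).
#' @param regimeCenters log10-ms locations of the ITI mixture components.
#' @param regimeSd log10-ms spread of each component.
#' @param baseLogits mixture-weight logits at the reference age of 50 years.
#' @param ageSlopes per-regime change of the weight logit per year of age.
#' @param regimePersistence probability of staying in the current regime for
#'   the next interval, in [0, 1].
#' @param subjectLogitSd standard deviation of a per-subject random offset
#'   added to the weight logits: stable individual differences in usage
#'   style, so that two subjects of the same age do not share an identical
#'   interval law.
#' @param accelerationYears additive effective-age offset for patients.
#' @param sessionsPerDay Poisson mean of usage sessions per day.
#' @param tapsPerSession Poisson mean of extra taps per session (each
#'   session has at least 2 taps).
#' @param seed integer seed; split into per-subject substreams so each
#'   subject is reproducible independently of cohort size.
#' @return a validated list of class \code{tapage_config}.
#' @export
generatorConfig <- function(nSubjects = 120L, nPatients = 0L,
                            ageRange = c(16, 86), daysRange = c(7L, 180L),
                            regimeCenters = c(fast = 2.0, medium = 3.0,
                                              slow = 3.6, gap = 4.5),
                            regimeSd = c(0.20, 0.25, 0.22, 0.30),
                            baseLogits = c(1.0, 0.8, 0.1, -0.9),
                            ageSlopes = c(-0.030, 0.000, 0.012, 0.024),
                            regimePersistence = 0.65,
                            subjectLogitSd = 0.25,
                            accelerationYears = 0,
                            sessionsPerDay = 20, tapsPerSession = 10,
                            seed = 1L) {
  stopifnot(length(ageRange) == 2, length(daysRange) == 2)
  if (ageRange[1] > ageRange[2] || daysRange[1] > daysRange[2])
    stop("invalid range: low > high")
  if (ageRange[1] < 16 || ageRange[2] > 86)
    warning("ageRange outside the default 16-86 year sampling span")
  if (regimePersistence < 0 || regimePersistence > 1)
    stop("regimePersistence must be in [0, 1]")
  k <- length(regimeCenters)
  stopifnot(length(regimeSd) == k, length(baseLogits) == k,
            length(ageSlopes) == k, all(regimeSd > 0),
            nSubjects >= 0, nPatients >= 0, daysRange[1] >= 1)
  structure(list(
    nSubjects = as.integer(nSubjects), nPatients = as.integer(nPatients),
    ageRange = ageRange, daysRange = as.integer(daysRange),
    regimeCenters = regimeCenters, regimeSd = regimeSd,
    baseLogits = baseLogits, ageSlopes = ageSlopes,
    regimePersistence = regimePersistence,
    subjectLogitSd = subjectLogitSd,
    accelerationYears = accelerationYears,
    sessionsPerDay = sessionsPerDay, tapsPerSession = tapsPerSession,
    seed = as.integer(seed)), class = "tapage_config")
}

#' Age-adjusted regime mixture weights
#'
#' The mixture weight of regime r at age a is
#' \code{softmax(baseLogits + ageSlopes * (a - 50))}, clipped implicitly to
#' (0, 1) and summing to 1 by construction. This closed form is the oracle
#' against which Monte-Carlo properties of the generator are checked.
#'
#' @param age age in years (effective age for patients).
#' @param config a \code{\link{generatorConfig}}.
#' @return numeric vector of mixture weights summing to 1.
#' @export
regimeWeights <- function(age, config) {
  logits <- config$baseLogits + config$ageSlopes * (age - 50)
  w <- exp(logits - max(logits))
  w / sum(w)
}

## Markov regime chain of length m: stay with prob `persistence`, otherwise
## redraw from the stationary weights. Vectorised fill-forward.
.regimeChain <- function(m, weights, persistence) {
  fresh <- sample.int(length(weights), m, replace = TRUE, prob = weights)
  if (m == 1L || persistence == 0) return(fresh)
  redraw <- c(TRUE, stats::runif(m - 1L) >= persistence)
  fresh[cummax(seq_len(m) * redraw)]
}

.sampleItis <- function(m, weights, config) {
  r <- .regimeChain(m, weights, config$regimePersistence)
  log10iti <- config$regimeCenters[r] +
    config$regimeSd[r] * stats::rnorm(m)
  pmax(1, round(10^log10iti))
}

## One subject's stream: days are independent; sessions per day are Poisson;
## inter-session gaps are lognormal (~5-15 min). Events beyond the day end
## are clipped; a day left with < 2 events is dropped.
.generateStream <- function(effectiveAge, nDays, config, logitOffset = 0) {
  logits <- config$baseLogits + config$ageSlopes * (effectiveAge - 50) +
    logitOffset
  w <- exp(logits - max(logits))
  weights <- w / sum(w)
  perDay <- vector("list", nDays)
  for (d in seq_len(nDays)) {
    nSess <- max(1L, stats::rpois(1, config$sessionsPerDay))
    sizes <- 2L + stats::rpois(nSess, config$tapsPerSession)
    iti <- .sampleItis(sum(sizes) - 1L, weights, config)
    ## replace the interval that bridges two sessions by a long pause
    bridge <- cumsum(sizes)[-nSess]
    if (length(bridge))
      iti[bridge] <- pmax(1, round(10^stats::rnorm(length(bridge), 5.7, 0.3)))
    t0 <- stats::runif(1, 0, 3.6e6)
    ts <- round(t0) + c(0, cumsum(iti))
    ts <- ts[ts < MS_PER_DAY]
    if (length(ts) >= 2L) perDay[[d]] <- ts + (d - 1L) * MS_PER_DAY
  }
  unlist(perDay, use.names = FALSE)
}

#' Generate a synthetic tappigraphy cohort
#'
#' Draws per-subject multi-day tap streams from the age-adjusted Markov
#' mixture of lognormal ITI regimes described in
#' \code{\link{generatorConfig}}. Patient subjects are generated at
#' effective age \code{chronological + accelerationYears}; their metadata
#' records the chronological age, so downstream deviation analysis should
#' recover the injected acceleration. Deterministic given the config seed;
#' the seed is split into per-subject substreams, so the first n subjects
#' are identical whatever the cohort size.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return a \code{\linkS4class{TapCohort}}.
#' @examples
#' cohort <- generateCohort(generatorConfig(nSubjects = 3, seed = 7,
#'                                          daysRange = c(7L, 10L)))
#' cohort
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "tapage_config"))
  nTot <- config$nSubjects + config$nPatients
  set.seed(config$seed)
  subjSeeds <- sample.int(.Machine$integer.max - 1L, nTot)
  isPatient <- seq_len(nTot) > config$nSubjects
  ids <- ifelse(isPatient,
                sprintf("P%04d", seq_len(nTot) - config$nSubjects),
                sprintf("S%04d", seq_len(nTot)))
  streams <- vector("list", nTot)
  meta <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    set.seed(subjSeeds[i])
    age <- stats::runif(1, config$ageRange[1], config$ageRange[2])
    gender <- stats::rbinom(1, 1, 0.5)
    screen <- round(stats::runif(1, 4.7, 6.7), 1)
    nDays <- sample(seq(config$daysRange[1], config$daysRange[2]), 1)
    offset <- stats::rnorm(length(config$baseLogits), 0,
                           config$subjectLogitSd)
    eff <- age + if (isPatient[i]) config$accelerationYears else 0
    ts <- .generateStream(eff, nDays, config, offset)
    streams[[i]] <- ts
    meta[[i]] <- data.frame(
      subject_id = ids[i], age_years = age, gender_code = gender,
      screen_size = screen,
      cohort_label = if (isPatient[i]) "patient" else "healthy",
      recording_days = length(unique(ts %/% MS_PER_DAY)))
  }
  names(streams) <- ids
  subjects <- if (nTot == 0L)
    data.frame(subject_id = character(), age_years = numeric(),
               gender_code = numeric(), screen_size = numeric(),
               cohort_label = character(), recording_days = integer())
  else do.call(rbind, meta)
  new("TapCohort", streams = streams, subjects = DataFrame(subjects))
}
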