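#' @include AllClasses.R
NULL

.conditionFields <- function(condition) {
  aud <- switch(condition,
    AaVa = "a", AbVb = "b", AbVa = "b", AaVb = "a", Aa = "a", Ab = "b", "none")
  vis <- switch(condition,
    AaVa = "a", AbVa = "a", Va = "a", AaVb = "b", AbVb = "b", Vb = "b",
    Vc = "c", "none")
  list(auditory_id = aud, visual_id = vis)
}

#' Default scheduling configuration
#'
#' Five conditioning days of 120 trials each. Days 1--4 present the two
#' reinforced cued pairs (AaVa rewarded, AbVb air-puffed) with ~25% un-cued
#' trials (Va, Vb, Vc); on day 5 the un-cued fraction drops to ~14% and a
#' previously unexperienced recombined pair (AbVa) appears on ~14% of cued
#' trials. Inter-stimulus intervals are drawn uniformly from [4, 12] s.
#'
#' @param days Integer vector of conditioning days.
#' @param trialsPerDay Trials per daily session.
#' @param reinforced Logical; `FALSE` gives the no-reinforcement paradigm
#'   (same stimuli, no reward/air puff).
#' @return A config list accepted by [makeTrialSchedule()].
#' @export
scheduleConfig <- function(days = 1:5, trialsPerDay = 120, reinforced = TRUE) {
  list(
    days = as.integer(days),
    trialsPerDay = as.integer(trialsPerDay),
    isiBounds = c(4, 12),
    stimDuration = 1,
    uncuedFraction = c(`1` = 0.25, `2` = 0.25, `3` = 0.25, `4` = 0.25, `5` = 0.14),
    vcFractionOfUncued = 0.5,
    abvaFractionOfCued = 0.14,  # day 5 only
    cuedStimuli = c("AaVa", "AbVb"),
    uncuedStimuli = c("Va", "Vb"),
    reinforced = reinforced,
    mouse = "m1",
    startPad = 10
  )
}

#' Generate a randomized conditioning trial schedule
#'
#' Draws per-trial conditions from the configured fractions (per-trial
#' multinomial, so realized counts show binomial sampling error around the
#' targets), assigns 1-s auditory then 1-s visual stimulus onsets for cued
#' trials, reinforcement onsets where applicable, and inter-stimulus
#' intervals drawn uniformly within the configured bounds. Identical
#' `(config, seed)` give byte-identical schedules.
#'
#' @param config List as from [scheduleConfig()].
#' @param seed Integer seed for the schedule stream.
#' @return A [TrialSchedule-class].
#' @examples
#' sched <- makeTrialSchedule(scheduleConfig(days = 1, trialsPerDay = 40), seed = 1)
#' sched
#' @export
makeTrialSchedule <- function(config = scheduleConfig(), seed = 1) {
  uf <- config$uncuedFraction
  if (any(uf < 0) || any(uf > 1))
    .configError("uncued fractions must lie in [0, 1]")
  if (config$vcFractionOfUncued < 0 || config$vcFractionOfUncued > 1 ||
      config$abvaFractionOfCued < 0 || config$abvaFractionOfCued > 1)
    .configError("condition fractions must lie in [0, 1]")
  if (diff(config$isiBounds) < 0)
    .configError("ISI bounds must be increasing")
  if (config$trialsPerDay < 1L) .configError("trialsPerDay must be >= 1")

  set.seed(as.integer(seed))
  rows <- vector("list", 0L)
  trialId <- 0L
  t <- 0
  for (day in config$days) {
    dayKey <- as.character(min(day, 5L))
    fUncued <- if (dayKey %in% names(uf)) uf[[dayKey]] else uf[[length(uf)]]
    # each daily session occupies its own stretch of the time axis
    t <- t + config$startPad
    for (i in seq_len(config$trialsPerDay)) {
      uncued <- stats::runif(1) < fUncued
      if (uncued) {
        # half of un-cued trials are the never-cued control Vc, the rest
        # split between the normally cued stimuli presented alone
        u <- stats::runif(1)
        condition <- if (u < config$vcFractionOfUncued) "Vc"
                     else config$uncuedStimuli[
                       1L + floor(stats::runif(1) * length(config$uncuedStimuli))]
      } else {
        condition <- if (day == 5L &&
                         stats::runif(1) < config$abvaFractionOfCued) "AbVa"
                     else config$cuedStimuli[
                       1L + floor(stats::runif(1) * length(config$cuedStimuli))]
      }
      ids <- .conditionFields(condition)
      cued <- ids$auditory_id != "none"
      audOn <- if (cued) t else NA_real_
      visOn <- if (cued) t + config$stimDuration else t
      reinforcement <- "none"
      reinOn <- NA_real_
      if (config$reinforced && condition %in% c("AaVa", "AbVb")) {
        reinforcement <- if (condition == "AaVa") "reward" else "airpuff"
        reinOn <- visOn + config$stimDuration
      }
      trialId <- trialId + 1L
      rows[[trialId]] <- data.frame(
        trial_id = trialId,
        session_id = sprintf("%s_d%d", config$mouse, day),
        mouse = config$mouse, day = as.integer(day), condition = condition,
        auditory_id = ids$auditory_id, visual_id = ids$visual_id,
        reinforcement = reinforcement, opto = "none",
        auditory_onset = audOn, visual_onset = visOn,
        reinforcement_onset = reinOn, stringsAsFactors = FALSE)
      trialEnd <- visOn + config$stimDuration +
        (if (reinforcement != "none") config$stimDuration else 0)
      t <- trialEnd + stats::runif(1, config$isiBounds[1L], config$isiBounds[2L])
    }
  }
  trials <- do.call(rbind, rows)
  methods::new("TrialSchedule", trials = trials,
    isiBounds = as.numeric(config$isiBounds),
    stimDuration = config$stimDuration,
    conditionFractions = list(uncued = uf,
                              vcOfUncued = config$vcFractionOfUncued,
                              abvaOfCued = config$abvaFractionOfCued))
}

#' Generate a receptive-field mapping schedule
#'
#' One-second visual stimuli presented at positions on a visual-space grid
#' (corridor coordinate x elevation, abstract units), each repeated
#' `nRepeats` times in randomized order. Trials carry `pos_x`/`pos_y`
#' columns and condition label `"rf"`.
#'
#' @param grid List with `nx`, `ny`, `xlim`, `ylim` (see [rfGrid()]).
#' @param nRepeats Presentations per grid position.
#' @param isiBounds Inter-stimulus interval bounds (s).
#' @param seed Integer seed.
#' @return A [TrialSchedule-class] with position-tagged trials.
#' @export
makeRfSchedule <- function(grid = rfGrid(), nRepeats = 2, isiBounds = c(2, 3),
                           seed = 1) {
  set.seed(as.integer(seed))
  xc <- .gridCenters(grid$xlim, grid$nx)
  yc <- .gridCenters(grid$ylim, grid$ny)
  pos <- expand.grid(pos_x = xc, pos_y = yc)
  pos <- pos[rep(seq_len(nrow(pos)), nRepeats), , drop = FALSE]
  pos <- pos[sample.int(nrow(pos)), , drop = FALSE]
  t <- 5
  n <- nrow(pos)
  onsets <- numeric(n)
  for (i in seq_len(n)) {
    onsets[i] <- t
    t <- t + 1 + stats::runif(1, isiBounds[1L], isiBounds[2L])
  }
  trials <- data.frame(
    trial_id = seq_len(n), session_id = "rf", mouse = "m1", day = 1L,
    condition = "rf", auditory_id = "none", visual_id = "a",
    reinforcement = "none", opto = "none",
    auditory_onset = NA_real_, visual_onset = onsets,
    reinforcement_onset = NA_real_,
    pos_x = pos$pos_x, pos_y = pos$pos_y, stringsAsFactors = FALSE)
  methods::new("TrialSchedule", trials = trials,
    isiBounds = as.numeric(isiBounds), stimDuration = 1,
    conditionFractions = list())
}

.gridCenters <- function(lim, n) lim[1L] + (seq_len(n) - 0.5) * diff(lim) / n

#' Write / read a trial schedule as CSV
#'
#' @param schedule A [TrialSchedule-class].
#' @param path CSV file path.
#' @return `readTrialSchedule` returns a [TrialSchedule-class];
#'   `writeTrialSchedule` returns `path` invisibly.
#' @export
writeTrialSchedule <- function(schedule, path) {
  utils::write.csv(trialInfo(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialSchedule
#' @param isiBounds,stimDuration Metadata not stored in the CSV.
#' @export
readTrialSchedule <- function(path, isiBounds = c(4, 12), stimDuration = 1) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  methods::new("TrialSchedule", trials = tr, isiBounds = isiBounds,
               stimDuration = stimDuration, conditionFractions = list())
}
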