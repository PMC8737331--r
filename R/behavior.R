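#' @include AllClasses.R
NULL

#' Detect lick events by voltage thresholding
#'
#' A lick event is registered at each upward threshold crossing of the
#' lick-sensor voltage; crossings within the refractory period of the
#' previous event are suppressed.
#'
#' @param voltage Numeric voltage series.
#' @param sampleRate Sample rate (Hz).
#' @param threshold Crossing threshold (V).
#' @param refractoryMs Refractory period (ms, >= 0).
#' @return Numeric vector of event times (s), strictly increasing.
#' @export
detectLicks <- function(voltage, sampleRate, threshold = 2.5,
                        refractoryMs = 50) {
  if (any(!is.finite(voltage))) .dataError("voltage contains non-finite samples")
  if (refractoryMs < 0) .configError("refractory period must be >= 0")
  above <- voltage >= threshold
  rising <- which(above & !c(FALSE, above[-length(above)]))
  times <- (rising - 1) / sampleRate
  if (!length(times)) return(numeric(0))
  keep <- times[1L]
  for (t in times[-1L])
    if (t - keep[length(keep)] >= refractoryMs / 1000) keep <- c(keep, t)
  keep
}

#' Quantify anticipatory licking per trial and per (condition, day)
#'
#' A trial is anticipatory when at least one lick event falls inside the
#' response window relative to the visual stimulus onset (default 267--1000
#' ms, i.e. during the visual-stimulus second before reinforcement).
#' Fractions of trials with a lick are computed per mouse per (condition,
#' day) and summarized across mice (mean +/- s.e.m.).
#'
#' @param events Lick event times (s), e.g. from [detectLicks()].
#' @param schedule A [TrialSchedule-class].
#' @param window_s Length-2 window `(start, end]` in seconds relative to
#'   visual onset.
#' @return List: `trials` (per-trial table with `any_lick`, `lick_count`),
#'   `fractions` (per condition/day: mean, sem, n mice).
#' @export
anticipatoryLicking <- function(events, schedule, window_s = c(0.267, 1.0)) {
  tr <- trialInfo(schedule)
  tr <- tr[!is.na(tr$visual_onset), , drop = FALSE]
  lo <- tr$visual_onset + window_s[1L]
  hi <- tr$visual_onset + window_s[2L]
  count <- vapply(seq_len(nrow(tr)),
                  function(i) sum(events > lo[i] & events <= hi[i]),
                  integer(1))
  trials <- data.frame(trial_id = tr$trial_id, mouse = tr$mouse,
                       condition = tr$condition, day = tr$day,
                       any_lick = count > 0L, lick_count = count,
                       stringsAsFactors = FALSE)
  perMouse <- stats::aggregate(any_lick ~ condition + day + mouse,
                               data = trials, FUN = mean)
  fr <- stats::aggregate(any_lick ~ condition + day, data = perMouse,
                         FUN = mean)
  names(fr)[names(fr) == "any_lick"] <- "fraction"
  fr$sem <- stats::aggregate(any_lick ~ condition + day, data = perMouse,
                             FUN = sem)$any_lick
  fr$n_mice <- stats::aggregate(any_lick ~ condition + day, data = perMouse,
                                FUN = length)$any_lick
  list(trials = trials, fractions = fr, perMouse = perMouse)
}

#' Split a trial tensor by licking behaviour
#'
#' Partitions trials into lick and no-lick subsets (disjoint and
#' exhaustive). An empty partition raises a warning and is returned as
#' `NULL`.
#'
#' @param tensor A [TrialTensor-class].
#' @param lickTrials Per-trial table with `trial_id` and `any_lick`
#'   (from [anticipatoryLicking()]).
#' @return List: `lick`, `noLick` (trial tensors or `NULL`), `sizes`.
#' @export
splitByLicking <- function(tensor, lickTrials) {
  tr <- trialInfo(tensor)
  idx <- match(tr$trial_id, lickTrials$trial_id)
  if (anyNA(idx)) .dataError("lick table does not cover all tensor trials")
  lick <- lickTrials$any_lick[idx]
  take <- function(sel) {
    if (!any(sel)) return(NULL)
    methods::new("TrialTensor",
      values = tensor@values[, sel, , drop = FALSE],
      relBins = relBins(tensor), trials = tr[sel, , drop = FALSE],
      alignTo = tensor@alignTo, frameRate = frameRate(tensor),
      dropped = tensor@dropped)
  }
  a <- take(lick); b <- take(!lick)
  if (is.null(a)) warning("no lick trials in this tensor")
  if (is.null(b)) warning("no no-lick trials in this tensor")
  list(lick = a, noLick = b, sizes = c(lick = sum(lick), noLick = sum(!lick)))
}

#' Iterative running-speed-matched trial resampling
#'
#' Removes, per iteration, the single fastest trial from the group with the
#' initially higher average running speed and the single slowest trial from
#' the initially lower group, until the initially higher group's mean drops
#' to or below the initially lower group's mean (with continuous speeds the
#' ordering is strictly flipped almost surely). Equal initial means
#' designate the first argument as the initially higher group, in which
#' case the stopping criterion already holds and nothing is removed; ties
#' among
#' fastest/slowest trials are broken by the earliest index. Matching only
#' changes trial membership, never trial data.
#'
#' @param speedsA,speedsB Per-trial mean running speeds of the two stimulus
#'   conditions (non-empty numeric vectors).
#' @return List: `keptA`, `keptB` (surviving indices into the inputs),
#'   `iterations`, `initiallyHigher` (`"A"` or `"B"`), and a per-iteration
#'   `log` of removed indices and group means.
#' @examples
#' speedMatchTrials(c(10, 2, 2), c(1, 1, 9))
#' @export
speedMatchTrials <- function(speedsA, speedsB) {
  if (!length(speedsA) || !length(speedsB))
    .dataError("both groups must be non-empty")
  aHigher <- mean(speedsA) >= mean(speedsB)   # tie: first-listed is 'higher'
  hi <- if (aHigher) speedsA else speedsB
  lo <- if (aHigher) speedsB else speedsA
  keptHi <- seq_along(hi); keptLo <- seq_along(lo)
  iter <- 0L
  log <- list()
  while (mean(hi[keptHi]) > mean(lo[keptLo])) {
    if (length(keptHi) <= 1L || length(keptLo) <= 1L)
      .dataError("speed matching exhausted a group after ", iter,
                 " iteration(s) without meeting the stopping criterion")
    iter <- iter + 1L
    dropHi <- keptHi[which.max(hi[keptHi])]   # fastest in the higher group
    dropLo <- keptLo[which.min(lo[keptLo])]   # slowest in the lower group
    keptHi <- setdiff(keptHi, dropHi)
    keptLo <- setdiff(keptLo, dropLo)
    log[[iter]] <- data.frame(iteration = iter, removed_higher = dropHi,
                              removed_lower = dropLo,
                              mean_higher = mean(hi[keptHi]),
                              mean_lower = mean(lo[keptLo]))
  }
  list(keptA = if (aHigher) keptHi else keptLo,
       keptB = if (aHigher) keptLo else keptHi,
       iterations = iter,
       initiallyHigher = if (aHigher) "A" else "B",
       log = if (length(log)) do.call(rbind, log) else
         data.frame(iteration = integer(0)))
}

#' Quantify running speed per trial
#'
#' Mean running speed in a window relative to visual onset, per trial, with
#' per-(condition, day) aggregates. Trials whose window is not covered by
#' the speed series are dropped and reported.
#'
#' @param speed Running-speed series (cm/s).
#' @param sampleRate Sample rate of `speed` (Hz).
#' @param schedule A [TrialSchedule-class].
#' @param window_s Length-2 window in seconds relative to visual onset.
#' @return List: `trials` (per-trial mean speeds), `aggregates`, `dropped`.
#' @export
quantifyRunning <- function(speed, sampleRate, schedule,
                            window_s = c(0.267, 1.0)) {
  tr <- trialInfo(schedule)
  tr <- tr[!is.na(tr$visual_onset), , drop = FALSE]
  tmax <- length(speed) / sampleRate
  mu <- rep(NA_real_, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    lo <- tr$visual_onset[i] + window_s[1L]
    hi <- tr$visual_onset[i] + window_s[2L]
    if (lo < 0 || hi > tmax) next
    i0 <- floor(lo * sampleRate) + 1L
    i1 <- min(ceiling(hi * sampleRate), length(speed))
    mu[i] <- mean(speed[i0:i1])
  }
  ok <- !is.na(mu)
  trials <- data.frame(trial_id = tr$trial_id[ok], mouse = tr$mouse[ok],
                       condition = tr$condition[ok], day = tr$day[ok],
                       mean_speed = mu[ok], stringsAsFactors = FALSE)
  agg <- stats::aggregate(mean_speed ~ condition + day, data = trials,
                          FUN = mean)
  agg$sem <- stats::aggregate(mean_speed ~ condition + day, data = trials,
                              FUN = sem)$mean_speed
  list(trials = trials, aggregates = agg,
       dropped = tr$trial_id[!ok])
}
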