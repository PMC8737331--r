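#' @include AllClasses.R
NULL

#' Simulate licking and running for a conditioning session
#'
#' Anticipatory licking is generated per trial as a Bernoulli draw with the
#' ground truth's per-(condition, day) probability; when a trial licks, a
#' short supra-threshold voltage pulse is placed uniformly within the
#' anticipatory quantification window of the visual-stimulus second
#' (`lickWindow`, default the 267--1000 ms response window, before
#' reinforcement), so the generative probability is exactly the
#' window-lick probability recovered downstream. Running speed is a
#' positive baseline with slow multiplicative noise and a multiplicative
#' dip during stimulus presentation (auditory + visual seconds).
#'
#' @param schedule A [TrialSchedule-class].
#' @param truth A [GroundTruth-class] (uses `lickProb` and `running`).
#' @param sampleRate Behavioural sample rate in Hz.
#' @param seed Integer seed for the behaviour stream.
#' @param pulseV,pulseMs Lick pulse height (V) and width (ms).
#' @param lickWindow Length-2 window (s, relative to visual onset) within
#'   which generated lick events fall.
#' @return A [BehaviorRecord-class] whose `lickEvents` are the generative
#'   event times.
#' @export
simulateBehavior <- function(schedule, truth, sampleRate = 100, seed = 1,
                             pulseV = 5, pulseMs = 30,
                             lickWindow = c(0.267, 1.0)) {
  if (sampleRate <= 0) .configError("sampleRate must be positive")
  lp <- truth@lickProb
  if (nrow(lp) && any(lp$prob < 0 | lp$prob > 1))
    .configError("lick probabilities must lie in [0, 1]")
  tr <- trialInfo(schedule)
  dur <- schedule@stimDuration
  duration <- max(tr$visual_onset, tr$auditory_onset, na.rm = TRUE) + dur + 8
  n <- ceiling(duration * sampleRate)
  tt <- (seq_len(n) - 1) / sampleRate

  set.seed(as.integer(seed))
  # licking ---------------------------------------------------------------
  voltage <- numeric(n)
  eventTimes <- numeric(0)
  for (i in seq_len(nrow(tr))) {
    key <- lp$day == min(tr$day[i], max(lp$day)) & lp$condition == tr$condition[i]
    p <- if (any(key)) lp$prob[which(key)[1L]] else 0
    if (stats::runif(1) < p) {
      eventTimes <- c(eventTimes,
                      tr$visual_onset[i] +
                        stats::runif(1, lickWindow[1L] + 0.02,
                                     lickWindow[2L] - 0.02))
    }
  }
  eventTimes <- sort(eventTimes)
  w <- max(1L, round(pulseMs / 1000 * sampleRate))
  for (et in eventTimes) {
    i0 <- floor(et * sampleRate) + 1L
    voltage[i0:min(i0 + w - 1L, n)] <- pulseV
  }

  # running ---------------------------------------------------------------
  rp <- truth@running
  alpha <- 1 - exp(-1 / (sampleRate * rp$noiseTau))
  slow <- stats::filter(stats::rnorm(n, 0, rp$noiseSd), 1 - alpha,
                        method = "recursive") * sqrt(2 * alpha - alpha^2)
  speed <- rp$baseline * (1 + as.numeric(slow))
  dip <- rep(1, n)
  for (i in seq_len(nrow(tr))) {
    t0 <- if (!is.na(tr$auditory_onset[i])) tr$auditory_onset[i]
          else tr$visual_onset[i]
    t1 <- tr$visual_onset[i] + dur
    dip[tt >= t0 & tt < t1] <- 1 - rp$dip
  }
  speed <- pmax(speed * dip, 0)

  methods::new("BehaviorRecord", lickVoltage = voltage,
               lickRate = as.numeric(sampleRate), speed = speed,
               speedRate = as.numeric(sampleRate), lickEvents = eventTimes)
}
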