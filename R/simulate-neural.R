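#' @include AllClasses.R kernel.R
NULL

# Core event-driven trace synthesis. `amps` is nRoi x nEvents (signed dF/F
# peak amplitudes); each event contributes amp * calciumResponse(t - onset).
# Frame f (1-based) samples the signal at its centre time (f - 0.5)/rate.
.simulateFromEvents <- function(onsets, durs, amps, roi, frameRate, nFrames,
                                seed) {
  nRoi <- nrow(roi)
  tc <- (seq_len(nFrames) - 0.5) / frameRate
  signal <- matrix(0, nRoi, nFrames)
  tauR <- roi$tau_rise[1L]; tauD <- roi$tau_decay[1L]
  sameKernel <- all(roi$tau_rise == tauR) && all(roi$tau_decay == tauD)
  for (e in seq_along(onsets)) {
    a <- amps[, e]
    if (all(a == 0)) next
    support <- .kernelSupport(max(roi$tau_rise), max(roi$tau_decay), durs[e])
    idx <- which(tc > onsets[e] & tc <= onsets[e] + support)
    if (!length(idx)) next
    if (sameKernel) {
      k <- calciumResponse(tc[idx] - onsets[e], tauR, tauD, durs[e])
      signal[, idx] <- signal[, idx] + a %o% k
    } else {
      for (i in which(a != 0)) {
        k <- calciumResponse(tc[idx] - onsets[e], roi$tau_rise[i],
                             roi$tau_decay[i], durs[e])
        signal[i, idx] <- signal[i, idx] + a[i] * k
      }
    }
  }
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(nRoi * nFrames), nRoi, nFrames) * roi$noise_sigma
  raw <- roi$baseline_f0 * (1 + signal + noise)
  raw <- pmax(raw, 1e-3)   # raw fluorescence is strictly positive
  rownames(raw) <- roi$roi_id
  methods::new("FluorescenceRecording", raw = raw,
               frameRate = as.numeric(frameRate), roiIds = roi$roi_id)
}

.suppressionFor <- function(truth, condition, day) {
  s <- truth@suppression
  row <- s[s$day == min(day, max(s$day)), , drop = FALSE]
  if (condition == "AaVa") row$reward
  else if (condition == "AbVb") row$airpuff
  else 0  # recombined (AbVa/AaVb) and un-cued stimuli are never suppressed
}

.visualAmplitude <- function(truth, trial) {
  r <- truth@roi
  if (trial$condition == "rf") {
    g <- exp(-((trial$pos_x - r$rf_x)^2 + (trial$pos_y - r$rf_y)^2) /
               (2 * r$rf_sigma^2))
    return(r$vis_amp_a * g)
  }
  switch(trial$visual_id,
         a = r$vis_amp_a, b = r$vis_amp_b, c = r$vis_amp_c,
         numeric(nrow(r)))
}

#' Simulate calcium traces for a conditioning session
#'
#' Event-driven generative model: each 1-s stimulus drives a per-ROI
#' response of amplitude tuning x (1 - suppression factor) for the paired
#' cued visual condition on that day (unsuppressed otherwise), convolved
#' with a difference-of-exponentials calcium kernel, plus i.i.d. Gaussian
#' dF/F noise. Raw fluorescence is `F0 * (1 + dFF)` with a per-ROI positive
#' baseline, so the synthetic recording is strictly positive and
#' median-normalization recovers the generative dF/F.
#'
#' @param schedule A [TrialSchedule-class].
#' @param truth A [GroundTruth-class].
#' @param frameRate Effective imaging rate (Hz).
#' @param seed Integer seed for the neural noise stream.
#' @param postPad Seconds of recording kept after the last trial.
#' @return List with `recording` (a [FluorescenceRecording-class]) and
#'   `roi` (the per-ROI generative record).
#' @export
simulateNeuralTraces <- function(schedule, truth, frameRate = 15, seed = 1,
                                 postPad = 8) {
  if (!nTrials(schedule)) .configError("schedule must contain trials")
  if (frameRate <= 0) .configError("frameRate must be positive")
  methods::validObject(truth)
  tr <- trialInfo(schedule)
  roi <- truth@roi
  onsets <- numeric(0); durs <- numeric(0); ampCols <- list()
  dur <- schedule@stimDuration
  for (i in seq_len(nrow(tr))) {
    trial <- tr[i, ]
    if (!is.na(trial$auditory_onset)) {
      audAmp <- switch(trial$auditory_id, a = roi$aud_amp_a,
                       b = roi$aud_amp_b, numeric(nrow(roi)))
      onsets <- c(onsets, trial$auditory_onset); durs <- c(durs, dur)
      ampCols[[length(ampCols) + 1L]] <- audAmp
    }
    if (!is.na(trial$visual_onset)) {
      vis <- .visualAmplitude(truth, trial) *
        (1 - .suppressionFor(truth, trial$condition, trial$day))
      onsets <- c(onsets, trial$visual_onset); durs <- c(durs, dur)
      ampCols[[length(ampCols) + 1L]] <- vis
    }
  }
  amps <- do.call(cbind, ampCols)
  lastEvent <- max(onsets + durs)
  nFrames <- ceiling((lastEvent + postPad) * frameRate)
  list(recording = .simulateFromEvents(onsets, durs, amps, roi, frameRate,
                                       nFrames, seed),
       roi = roi)
}

#' Simulate an optogenetic influence-mapping session
#'
#' One-second optogenetic stimulation events drive per-ROI responses whose
#' sign and magnitude equal the roster's influence weight (`fmi_pre` or
#' `fmi_post`); interleaved sham light stimulations drive a per-ROI
#' response drawn independently of the influence weight, so opto and sham
#' responses are uncorrelated by construction.
#'
#' @param truth A [GroundTruth-class] whose `roi` carries `fmi_pre` /
#'   `fmi_post`.
#' @param nTrials Number of opto stimulation trials (>= 2).
#' @param phase `"pre"` or `"post"` conditioning (selects the weight set).
#' @param includeSham Interleave an equal number of sham trials.
#' @param frameRate Effective imaging rate (Hz).
#' @param isiBounds Interval between stimulations (s).
#' @param seed Integer seed.
#' @return List with `recording`, `schedule` (conditions `"opto"`/`"sham"`,
#'   onsets in `opto_onset`), and `roi`.
#' @export
simulateOptoSession <- function(truth, nTrials = 20,
                                phase = c("pre", "post"),
                                includeSham = TRUE, frameRate = 15,
                                isiBounds = c(6, 10), seed = 1) {
  phase <- match.arg(phase)
  if (nTrials < 2) .configError("nTrials must be >= 2 (variance undefined below)")
  roi <- truth@roi
  weights <- if (phase == "pre") roi$fmi_pre else roi$fmi_post
  set.seed(childSeed(seed, "opto_layout"))
  shamAmp <- stats::rnorm(nrow(roi), 0, 0.05)

  conds <- if (includeSham) rep(c("opto", "sham"), nTrials)[
                seq_len(2L * nTrials)] else rep("opto", nTrials)
  conds <- sample(conds)
  n <- length(conds)
  t <- 10; onsets <- numeric(n)
  for (i in seq_len(n)) {
    onsets[i] <- t
    t <- t + 1 + stats::runif(1, isiBounds[1L], isiBounds[2L])
  }
  amps <- vapply(seq_len(n), function(i)
    if (conds[i] == "opto") weights else shamAmp, numeric(nrow(roi)))
  rec <- .simulateFromEvents(onsets, rep(1, n), amps, roi, frameRate,
                             ceiling((max(onsets) + 9) * frameRate),
                             childSeed(seed, "opto_noise"))
  trials <- data.frame(
    trial_id = seq_len(n), session_id = paste0("fmi_", phase), mouse = "m1",
    day = if (phase == "pre") 0L else 6L, condition = conds,
    auditory_id = "none", visual_id = "none", reinforcement = "none",
    opto = ifelse(conds == "opto", "axon_stim", "sham"),
    auditory_onset = NA_real_, visual_onset = NA_real_,
    reinforcement_onset = NA_real_, opto_onset = onsets,
    stringsAsFactors = FALSE)
  sched <- methods::new("TrialSchedule", trials = trials,
                        isiBounds = as.numeric(isiBounds), stimDuration = 1,
                        conditionFractions = list())
  list(recording = rec, schedule = sched, roi = roi)
}
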