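# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# minimal hand-built schedule with onsets on the frame grid
gridSchedule <- function(onsets, condition = "Va", day = 1L,
                         auditory = FALSE, isi = c(25, 35)) {
  n <- length(onsets)
  cond1 <- rep_len(condition, n)
  audId <- ifelse(grepl("^A[ab]", cond1), sub("^A([ab]).*", "\\1", cond1), "none")
  visId <- sub(".*V([abc])$", "\\1", cond1)
  visId[!grepl("V[abc]$", cond1)] <- "none"
  tr <- data.frame(
    trial_id = seq_len(n), session_id = "s", mouse = "m1",
    day = rep_len(as.integer(day), n), condition = cond1,
    auditory_id = audId, visual_id = visId,
    reinforcement = "none", opto = "none",
    auditory_onset = ifelse(audId == "none", NA_real_, onsets - 1),
    visual_onset = onsets, reinforcement_onset = NA_real_,
    stringsAsFactors = FALSE)
  methods::new("TrialSchedule", trials = tr, isiBounds = isi,
               stimDuration = 1, conditionFractions = list())
}

# tiny recording with explicit raw values
toyRecording <- function(raw, frameRate = 15) {
  raw <- rbind(raw)
  rownames(raw) <- sprintf("roi%04d", seq_len(nrow(raw)))
  methods::new("FluorescenceRecording", raw = raw, frameRate = frameRate,
               roiIds = rownames(raw))
}

# tensor built directly from an array (roi x trial x relative frame)
toyTensor <- function(values, relBins, condition = "Va", day = 1L,
                      frameRate = 15) {
  nTrial <- dim(values)[2L]
  dimnames(values) <- list(sprintf("roi%04d", seq_len(dim(values)[1L])),
                           seq_len(nTrial), as.character(relBins))
  tr <- data.frame(trial_id = seq_len(nTrial), session_id = "s",
                   mouse = "m1", day = rep_len(as.integer(day), nTrial),
                   condition = rep_len(condition, nTrial),
                   auditory_id = "none", visual_id = "a",
                   reinforcement = "none", opto = "none",
                   auditory_onset = NA_real_, visual_onset = NA_real_,
                   reinforcement_onset = NA_real_, stringsAsFactors = FALSE)
  methods::new("TrialTensor", values = values, relBins = as.integer(relBins),
               trials = tr, alignTo = "visual_onset", frameRate = frameRate,
               dropped = data.frame())
}

# brute-force windowed response: naive loops, independent of the pipeline
bruteResponse <- function(values, relBins, respBins, baseBins) {
  nRoi <- dim(values)[1L]; nTrial <- dim(values)[2L]
  out <- matrix(NA_real_, nRoi, nTrial)
  for (i in seq_len(nRoi)) for (j in seq_len(nTrial)) {
    r <- 0; for (b in respBins) r <- r + values[i, j, which(relBins == b)]
    bl <- 0; for (b in baseBins) bl <- bl + values[i, j, which(relBins == b)]
    out[i, j] <- r / length(respBins) - bl / length(baseBins)
  }
  out
}

# exact probability of at least one run of >= m successes in n independent
# Bernoulli(p) trials, by dynamic programming over trailing run length
# (state[k+1] = P(trailing run length k, no run of m seen yet))
runProbabilityExact <- function(n, p, m) {
  state <- c(1, numeric(m - 1))
  hit <- 0
  for (i in seq_len(n)) {
    new <- numeric(m)
    new[1] <- sum(state) * (1 - p)
    if (m > 1) for (k in 1:(m - 1)) new[k + 1] <- state[k] * p
    hit <- hit + state[m] * p
    state <- new
  }
  hit
}
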