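#' @include AllClasses.R
NULL

# first frame (1-based) starting at or after `onset` seconds
.onsetFrame <- function(onset, frameRate) {
  as.integer(ceiling(onset * frameRate - 1e-9)) + 1L
}

#' Align dF/F traces to trial events
#'
#' Cuts an ROI x trial x relative-frame block around each trial's alignment
#' onset. Relative frame 0 is the frame at or immediately after the onset
#' (frames are assigned by their start time). Trials whose window exceeds
#' the recording bounds, or whose alignment onset is absent, are dropped
#' and logged in the tensor's `@dropped` slot.
#'
#' @param dffSet A [DffTraceSet-class].
#' @param schedule A [TrialSchedule-class].
#' @param alignTo Onset column: `"visual_onset"`, `"auditory_onset"` or
#'   `"opto_onset"`.
#' @param window Integer `c(pre, post)`: frames kept before/after the onset
#'   frame (the block spans relative frames `-pre .. post`).
#' @return A [TrialTensor-class].
#' @export
alignTrials <- function(dffSet, schedule,
                        alignTo = c("visual_onset", "auditory_onset",
                                    "opto_onset"),
                        window = c(pre = 15, post = 30)) {
  alignTo <- match.arg(alignTo)
  tr <- trialInfo(schedule)
  if (!alignTo %in% colnames(tr))
    .dataError("schedule has no column ", alignTo)
  x <- dff(dffSet)
  rate <- frameRate(dffSet)
  pre <- as.integer(window[1L]); post <- as.integer(window[2L])
  relBins <- seq.int(-pre, post)
  nFrames <- ncol(x)

  keep <- logical(nrow(tr))
  reason <- character(nrow(tr))
  f0 <- rep(NA_integer_, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    onset <- tr[[alignTo]][i]
    if (is.na(onset)) { reason[i] <- "no alignment onset"; next }
    fi <- .onsetFrame(onset, rate)
    if (fi - pre < 1L || fi + post > nFrames) {
      reason[i] <- "window outside recording"; next
    }
    keep[i] <- TRUE
    f0[i] <- fi
  }
  if (!any(keep)) .dataError("no trial window lies within the recording")
  kept <- which(keep)
  values <- array(NA_real_, c(nrow(x), length(kept), length(relBins)),
                  dimnames = list(rownames(x), tr$trial_id[kept],
                                  as.character(relBins)))
  for (j in seq_along(kept))
    values[, j, ] <- x[, (f0[kept[j]] - pre):(f0[kept[j]] + post), drop = FALSE]
  dropped <- data.frame(trial_id = tr$trial_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  methods::new("TrialTensor", values = values, relBins = as.integer(relBins),
               trials = tr[kept, , drop = FALSE], alignTo = alignTo,
               frameRate = rate, dropped = dropped)
}

# mean over a set of third-axis slices, kept as an ROI x trial matrix
.sliceMean <- function(v, idx) {
  out <- matrix(0, dim(v)[1L], dim(v)[2L])
  for (k in idx) out <- out + matrix(v[, , k], dim(v)[1L], dim(v)[2L])
  out / length(idx)
}

# positions of relative bins within the tensor's third axis
.binIndex <- function(tensor, bins) {
  idx <- match(bins, relBins(tensor))
  if (anyNA(idx))
    .dataError("tensor window does not cover requested bins ",
               paste(bins[is.na(idx)], collapse = ", "))
  idx
}

#' Quantify windowed, baseline-subtracted trial responses
#'
#' The per-(ROI, trial) scalar response is the mean dF/F over the response
#' window minus the mean over the baseline window (e.g. 267--1000 ms after
#' visual onset minus -667--0 ms before it).
#'
#' @param tensor A [TrialTensor-class] covering both windows.
#' @param window A [WindowSpec-class].
#' @param aggregationUnit Aggregation unit recorded on the result
#'   (`"roi"` across neurons/axons, `"mouse"` across animals).
#' @return A [ResponseTable-class] (tidy: roi_id, trial_id, condition, day,
#'   response, plus mouse and any event covariates present).
#' @export
quantifyResponse <- function(tensor, window = windowSpec(frameRate(tensor)),
                             aggregationUnit = "roi") {
  ri <- .binIndex(tensor, responseBins(window))
  bi <- .binIndex(tensor, baselineBins(window))
  v <- tensor@values
  resp <- .sliceMean(v, ri) - .sliceMean(v, bi)
  rownames(resp) <- roiIds(tensor)
  tr <- trialInfo(tensor)
  tab <- data.frame(
    roi_id = rep(rownames(resp), times = ncol(resp)),
    trial_id = rep(tr$trial_id, each = nrow(resp)),
    mouse = rep(tr$mouse, each = nrow(resp)),
    condition = rep(tr$condition, each = nrow(resp)),
    day = rep(tr$day, each = nrow(resp)),
    response = as.vector(resp), stringsAsFactors = FALSE)
  for (cc in intersect(c("pos_x", "pos_y", "opto"), colnames(tr)))
    tab[[cc]] <- rep(tr[[cc]], each = nrow(resp))
  methods::new("ResponseTable", table = tab,
               aggregationUnit = aggregationUnit, window = window)
}

#' Per-ROI mean responses for a condition/day slice
#'
#' Averages per-trial responses across trials, per ROI, for one condition
#' (optionally restricted to days), returning a named vector in ROI order.
#'
#' @param responseTable A [ResponseTable-class].
#' @param condition Condition label(s) to include.
#' @param day Optional day(s) to include.
#' @return Named numeric vector of per-ROI mean responses.
#' @export
roiMeans <- function(responseTable, condition, day = NULL) {
  tab <- responses(responseTable)
  sel <- tab$condition %in% condition
  if (!is.null(day)) sel <- sel & tab$day %in% day
  if (!any(sel)) .dataError("no responses for the requested slice")
  tab <- tab[sel, , drop = FALSE]
  out <- tapply(tab$response, tab$roi_id, mean)
  out[unique(responses(responseTable)$roi_id)]
}

#' Population summary of a response slice
#'
#' Mean and s.e.m. across the aggregation unit (per-ROI means are computed
#' across trials first, then summarized across ROIs).
#'
#' @inheritParams roiMeans
#' @return List: `mean`, `sem`, `n`, `unit`.
#' @export
populationSummary <- function(responseTable, condition, day = NULL) {
  m <- roiMeans(responseTable, condition, day)
  list(mean = mean(m), sem = sem(m), n = length(m),
       unit = responseTable@aggregationUnit)
}
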