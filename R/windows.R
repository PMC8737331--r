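#' Convert a millisecond interval to relative frame bins
#'
#' Frames are one-frame (e.g. 66.7 ms at 15 Hz) time bins indexed relative to
#' an alignment onset: bin 0 is the frame at or immediately after the onset.
#' A bin belongs to the interval when its centre time lies within
#' `(start_ms, end_ms]` (half-open on the left). At the 15 Hz effective rate
#' of four-plane resonant imaging this maps 267--1000 ms onto 11 bins and
#' -667--0 ms onto 10 bins.
#'
#' @param frameRate Effective frame rate in Hz (> 0).
#' @param interval Numeric length-2, `(start_ms, end_ms]` relative to onset;
#'   `end_ms > start_ms`.
#' @return Integer vector of contiguous relative frame indices.
#' @examples
#' timeToBins(15, c(267, 1000))   # 11 response bins
#' timeToBins(15, c(-667, 0))     # 10 baseline bins
#' @export
timeToBins <- function(frameRate, interval) {
  if (!is.numeric(frameRate) || length(frameRate) != 1L || frameRate <= 0)
    .configError("frameRate must be a single positive number")
  if (length(interval) != 2L || !is.numeric(interval))
    .configError("interval must be numeric length 2 (start_ms, end_ms)")
  start <- interval[1L]; end <- interval[2L]
  if (end <= start) .configError("interval end must exceed its start")
  period <- 1000 / frameRate
  eps <- 1e-6
  kmin <- floor(start / period - 1)
  kmax <- ceiling(end / period + 1)
  k <- seq.int(kmin, kmax)
  centre <- (k + 0.5) * period
  k[centre > start + eps & centre <= end + eps]
}

#' Effective per-plane frame rate of multi-plane acquisition
#'
#' Sequential plane scanning divides the acquisition rate across planes:
#' 60 Hz across four planes gives 15 Hz per imaging plane.
#'
#' @param acquisitionRate Full acquisition frame rate in Hz.
#' @param nPlanes Number of sequentially scanned planes.
#' @return Per-plane frame rate in Hz.
#' @export
effectiveFrameRate <- function(acquisitionRate, nPlanes) {
  stopifnot(acquisitionRate > 0, nPlanes >= 1)
  acquisitionRate / nPlanes
}

#' Construct a response/baseline window specification
#'
#' Defaults reproduce the standard peri-stimulus quantification windows:
#' response 267--1000 ms after visual stimulus onset (11 frames at 15 Hz)
#' and baseline -667--0 ms before it (10 frames). With cued stimuli the
#' baseline window deliberately sits inside the auditory second, so windowed
#' responses are measured net of auditory-period activity.
#'
#' @param frameRate Effective frame rate in Hz.
#' @param baseline_ms,response_ms Length-2 millisecond intervals relative to
#'   the alignment onset.
#' @return A [WindowSpec-class] object.
#' @export
windowSpec <- function(frameRate = 15,
                       baseline_ms = c(-667, 0),
                       response_ms = c(267, 1000)) {
  methods::new("WindowSpec",
    baselineBins = as.integer(timeToBins(frameRate, baseline_ms)),
    responseBins = as.integer(timeToBins(frameRate, response_ms)),
    frameRate = as.numeric(frameRate))
}
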