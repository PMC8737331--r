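#' Calcium-indicator impulse and stimulus response kernels
#'
#' The indicator kernel is a difference of exponentials
#' `h(t) = (exp(-t/tauDecay) - exp(-t/tauRise)) / (tauDecay - tauRise)`
#' (unit area, `t >= 0`). A 1-s stimulus drives the boxcar convolution of
#' `h`, which has the closed form `F(t) - F(t - dur)` with
#' `F(t) = 1 - (tauDecay exp(-t/tauDecay) - tauRise exp(-t/tauRise)) /
#' (tauDecay - tauRise)`. `calciumResponse()` rescales this so its peak
#' (reached just after stimulus offset) is 1, making generative amplitudes peak
#' dF/F values.
#'
#' @param t Time in seconds (vector); values before the event return 0.
#' @param tauRise,tauDecay Kernel time constants in seconds
#'   (`tauDecay > tauRise > 0`). Defaults are GCaMP6f-like.
#' @param dur Stimulus duration in seconds.
#' @return Numeric vector of kernel values.
#' @examples
#' calciumResponse(seq(0, 3, 0.1))
#' @export
calciumResponse <- function(t, tauRise = 0.05, tauDecay = 0.6, dur = 1) {
  stopifnot(tauRise > 0, tauDecay > tauRise, dur > 0)
  r <- .stepResponse(t, tauRise, tauDecay) -
       .stepResponse(t - dur, tauRise, tauDecay)
  r / .peakResponse(tauRise, tauDecay, dur)
}

# peak of the un-normalized boxcar response (just after stimulus offset)
.peakResponse <- function(tauRise, tauDecay, dur) {
  stats::optimize(function(t) .stepResponse(t, tauRise, tauDecay) -
                    .stepResponse(t - dur, tauRise, tauDecay),
                  c(dur, dur + 3 * tauRise * log(1 + tauDecay / tauRise)),
                  maximum = TRUE, tol = 1e-12)$objective
}

.stepResponse <- function(t, tauRise, tauDecay) {
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- 1 - (tauDecay * exp(-tp / tauDecay) -
                   tauRise * exp(-tp / tauRise)) / (tauDecay - tauRise)
  out
}

# time after event onset beyond which the normalized response is < tol
.kernelSupport <- function(tauRise, tauDecay, dur = 1, tol = 1e-12) {
  dur + tauDecay * log(1 / tol)
}

#' Expected windowed response to a unit-amplitude stimulus
#'
#' The noise-free expectation of the baseline-subtracted windowed response
#' scalar for a unit-amplitude event, given the alignment/window
#' conventions: mean of [calciumResponse()] at the response-bin centres
#' minus its mean at the baseline-bin centres. Used as the closed-form
#' oracle for parameter-recovery tests: a generative amplitude `a` yields
#' an expected response `a * windowGain(...)`.
#'
#' @param window A [WindowSpec-class].
#' @param tauRise,tauDecay,dur Kernel parameters (see [calciumResponse()]).
#' @param onsetOffset Time from the aligned event onset to the start of
#'   relative frame 0, in seconds (0 when onsets lie on the frame grid).
#' @return The dimensionless window gain.
#' @export
windowGain <- function(window, tauRise = 0.05, tauDecay = 0.6, dur = 1,
                       onsetOffset = 0) {
  rate <- frameRate(window)
  centre <- function(k) (k + 0.5) / rate + onsetOffset
  mean(calciumResponse(centre(responseBins(window)), tauRise, tauDecay, dur)) -
    mean(calciumResponse(centre(baselineBins(window)), tauRise, tauDecay, dur))
}
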