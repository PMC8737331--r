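#' @include AllClasses.R
NULL

#' Compute median-normalized dF/F traces
#'
#' `dFF[i, t] = (F[i, t] - median_i) / median_i` with `median_i` the median
#' of ROI i's raw trace over the whole recording. ROIs with non-positive
#' median are excluded, with the exclusion logged in the provenance (the
#' normalization is undefined for them). Optionally a causal exponential
#' smoothing filter is applied after normalization; the default is no
#' filtering, and either choice is recorded in the provenance.
#'
#' @param recording A [FluorescenceRecording-class].
#' @param filterTau Optional time constant (s) of a causal exponential
#'   filter; `NULL` (default) applies no smoothing.
#' @return A [DffTraceSet-class].
#' @examples
#' rec <- methods::new("FluorescenceRecording",
#'   raw = matrix(c(1, 1, 1, 3), 1), frameRate = 15, roiIds = "r1")
#' dff(computeDff(rec))  # 0 0 0 2
#' @export
computeDff <- function(recording, filterTau = NULL) {
  raw <- rawTrace(recording)
  med <- apply(raw, 1L, stats::median)
  bad <- med <= 0
  if (any(bad)) {
    message(sum(bad), " ROI(s) excluded: non-positive raw median (",
            paste(roiIds(recording)[bad], collapse = ", "), ")")
    raw <- raw[!bad, , drop = FALSE]
    med <- med[!bad]
  }
  if (!nrow(raw)) .dataError("no ROI with positive median raw fluorescence")
  out <- (raw - med) / med
  filterDesc <- "none"
  if (!is.null(filterTau)) {
    if (filterTau <= 0) .configError("filterTau must be positive")
    alpha <- 1 - exp(-1 / (frameRate(recording) * filterTau))
    for (i in seq_len(nrow(out)))
      out[i, ] <- stats::filter(alpha * out[i, ], 1 - alpha,
                                method = "recursive", init = out[i, 1L])
    filterDesc <- sprintf("causal exponential, tau = %g s", filterTau)
  }
  methods::new("DffTraceSet", dff = out, medians = med,
               frameRate = frameRate(recording),
               provenance = list(normalization = "median", filter = filterDesc,
                                 excluded = roiIds(recording)[bad]))
}
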