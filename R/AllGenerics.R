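#' @include AllClasses.R
NULL

#' Accessors for crossmodal classes
#'
#' `frameRate()` returns the effective imaging rate in Hz; `nRoi()` and
#' `roiIds()` the ROI count/identifiers; `trialInfo()` the trial metadata
#' table; `dff()` the dF/F matrix; `rawTrace()` the raw fluorescence matrix;
#' `responses()` the tidy per-trial response table; `relBins()` the relative
#' frame bins of a trial tensor.
#'
#' @param object A crossmodal S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("nRoi", function(object) standardGeneric("nRoi"))
#' @rdname accessors
#' @export
setGeneric("roiIds", function(object) standardGeneric("roiIds"))
#' @rdname accessors
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))
#' @rdname accessors
#' @export
setGeneric("dff", function(object) standardGeneric("dff"))
#' @rdname accessors
#' @export
setGeneric("rawTrace", function(object) standardGeneric("rawTrace"))
#' @rdname accessors
#' @export
setGeneric("responses", function(object) standardGeneric("responses"))
#' @rdname accessors
#' @export
setGeneric("relBins", function(object) standardGeneric("relBins"))
#' @rdname accessors
#' @export
setGeneric("baselineBins", function(object) standardGeneric("baselineBins"))
#' @rdname accessors
#' @export
setGeneric("responseBins", function(object) standardGeneric("responseBins"))

setMethod("frameRate", "FluorescenceRecording", function(object) object@frameRate)
setMethod("frameRate", "DffTraceSet", function(object) object@frameRate)
setMethod("frameRate", "TrialTensor", function(object) object@frameRate)
setMethod("frameRate", "WindowSpec", function(object) object@frameRate)

setMethod("nRoi", "FluorescenceRecording", function(object) nrow(object@raw))
setMethod("nRoi", "DffTraceSet", function(object) nrow(object@dff))
setMethod("nRoi", "TrialTensor", function(object) dim(object@values)[1L])

setMethod("roiIds", "FluorescenceRecording", function(object) object@roiIds)
setMethod("roiIds", "DffTraceSet", function(object) rownames(object@dff))
setMethod("roiIds", "TrialTensor", function(object) dimnames(object@values)[[1L]])

setMethod("trialInfo", "TrialSchedule", function(object) object@trials)
setMethod("trialInfo", "TrialTensor", function(object) object@trials)

setMethod("dff", "DffTraceSet", function(object) object@dff)
setMethod("rawTrace", "FluorescenceRecording", function(object) object@raw)
setMethod("responses", "ResponseTable", function(object) object@table)
setMethod("relBins", "TrialTensor", function(object) object@relBins)
setMethod("baselineBins", "WindowSpec", function(object) object@baselineBins)
setMethod("responseBins", "WindowSpec", function(object) object@responseBins)

#' Number of trials in a schedule or tensor
#' @param object A `TrialSchedule` or `TrialTensor`.
#' @return Integer trial count.
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
setMethod("nTrials", "TrialSchedule", function(object) nrow(object@trials))
setMethod("nTrials", "TrialTensor", function(object) dim(object@values)[2L])

setMethod("show", "WindowSpec", function(object) {
  cat("WindowSpec @", object@frameRate, "Hz\n")
  cat("  baseline bins:", paste(range(object@baselineBins), collapse = ".."),
      sprintf("(%d frames)\n", length(object@baselineBins)))
  cat("  response bins:", paste(range(object@responseBins), collapse = ".."),
      sprintf("(%d frames)\n", length(object@responseBins)))
})

setMethod("show", "TrialSchedule", function(object) {
  tr <- object@trials
  cat(sprintf("TrialSchedule: %d trials, days %s, ISI [%g, %g] s\n",
              nrow(tr), paste(sort(unique(tr$day)), collapse = ","),
              object@isiBounds[1L], object@isiBounds[2L]))
  print(table(condition = tr$condition, day = tr$day))
})

setMethod("show", "FluorescenceRecording", function(object) {
  cat(sprintf("FluorescenceRecording: %d ROIs x %d frames @ %g Hz (%.1f s)\n",
              nrow(object@raw), ncol(object@raw), object@frameRate,
              ncol(object@raw) / object@frameRate))
})

setMethod("show", "DffTraceSet", function(object) {
  cat(sprintf("DffTraceSet: %d ROIs x %d frames @ %g Hz\n",
              nrow(object@dff), ncol(object@dff), object@frameRate))
  if (!is.null(object@provenance$filter))
    cat("  filter:", object@provenance$filter, "\n")
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("TrialTensor: %d ROIs x %d trials x %d frames, aligned to %s\n",
              d[1L], d[2L], d[3L], object@alignTo))
  if (nrow(object@dropped))
    cat(sprintf("  %d trial(s) dropped (see @dropped)\n", nrow(object@dropped)))
})

setMethod("show", "ResponseTable", function(object) {
  cat(sprintf("ResponseTable: %d responses, %d ROIs, aggregation unit '%s'\n",
              nrow(object@table), length(unique(object@table$roi_id)),
              object@aggregationUnit))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d %s ROIs\n", nrow(object@roi), object@population))
  cat("  reward-pairing suppression by day:",
      paste(signif(object@suppression$reward, 3), collapse = " "), "\n")
})

setMethod("show", "ResponseDifferenceResult", function(object) {
  cat(sprintf("Response difference index: %.4f +/- %.4f (n = %d ROIs)\n",
              object@mean, object@sem, length(object@perRoi)))
  cat(sprintf("  vs 0: %s, p = %.3g\n", object@test$test, object@test$p.value))
})

setMethod("show", "BinwiseTestResult", function(object) {
  cat(sprintf("Binwise %s: %d/%d bins flagged (alpha = %g, runs >= %d bins)\n",
              object@test, sum(object@significant), length(object@bins),
              object@alpha, object@minConsecutive))
})

setMethod("show", "ReceptiveFieldMap", function(object) {
  cat(sprintf("ReceptiveFieldMap: %d x %d grid, %d events, %s\n",
              length(object@xCenters), length(object@yCenters),
              sum(object@n, na.rm = TRUE),
              if (is.na(object@normConstant)) "raw"
              else sprintf("peak-normalized (constant %.4g)", object@normConstant)))
})

setMethod("show", "BehaviorRecord", function(object) {
  cat(sprintf("BehaviorRecord: %.1f s lick voltage @ %g Hz, %.1f s speed @ %g Hz, %d lick events\n",
              length(object@lickVoltage) / object@lickRate, object@lickRate,
              length(object@speed) / object@speedRate, object@speedRate,
              length(object@lickEvents)))
})
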