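#' @import methods
NULL

.CUED_CONDITIONS   <- c("AaVa", "AbVb", "AbVa", "AaVb")
.UNCUED_CONDITIONS <- c("Va", "Vb", "Vc")
.AUD_CONDITIONS    <- c("Aa", "Ab")
.ALL_CONDITIONS    <- c(.CUED_CONDITIONS, .UNCUED_CONDITIONS, .AUD_CONDITIONS,
                        "rf", "opto", "sham")

.SCHEDULE_COLS <- c("trial_id", "session_id", "mouse", "day", "condition",
                    "auditory_id", "visual_id", "reinforcement", "opto",
                    "auditory_onset", "visual_onset", "reinforcement_onset")

#' Class of peri-stimulus quantification windows
#'
#' Holds the baseline and response windows as relative frame-bin indices
#' (bin 0 = frame at/after the alignment onset). Baseline bins must strictly
#' precede the onset and never overlap the response bins.
#'
#' @slot baselineBins integer vector of relative bins, all < 0.
#' @slot responseBins integer vector of relative bins, all >= 0.
#' @slot frameRate effective frame rate (Hz).
#' @seealso [windowSpec()]
#' @export
setClass("WindowSpec",
  representation(baselineBins = "integer", responseBins = "integer",
                 frameRate = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive number")
    if (any(object@baselineBins >= 0))
      msg <- c(msg, "baseline bins must strictly precede the onset")
    if (any(object@responseBins < 0))
      msg <- c(msg, "response bins must follow the onset")
    if (length(intersect(object@baselineBins, object@responseBins)))
      msg <- c(msg, "baseline and response windows must be disjoint")
    if (is.null(msg)) TRUE else msg
  })

#' Class of conditioning trial schedules
#'
#' An ordered table of stimulus/reinforcement events. Each trial carries a
#' condition label (`AaVa`, `AbVb`, `Va`, `Vb`, `Vc`, `AbVa`, ...), onset
#' times in seconds, and session/day bookkeeping. Cued trials present a 1-s
#' auditory stimulus immediately followed by a 1-s visual stimulus; the
#' reinforcement, when present, follows the visual stimulus.
#'
#' @slot trials data.frame of trials (one row per trial, in temporal order).
#' @slot isiBounds length-2 numeric, inter-stimulus interval bounds (s).
#' @slot stimDuration stimulus duration in seconds (auditory and visual).
#' @slot conditionFractions named list recording the requested fractions.
#' @export
setClass("TrialSchedule",
  representation(trials = "data.frame", isiBounds = "numeric",
                 stimDuration = "numeric", conditionFractions = "list"),
  validity = function(object) {
    tr <- object@trials
    msg <- NULL
    missing <- setdiff(.SCHEDULE_COLS, colnames(tr))
    if (length(missing))
      msg <- c(msg, paste("missing trial columns:", paste(missing, collapse = ", ")))
    if (length(object@isiBounds) != 2L || diff(object@isiBounds) < 0)
      msg <- c(msg, "isiBounds must be an increasing length-2 numeric")
    if (!is.null(msg)) return(msg)
    if (nrow(tr)) {
      cued <- !is.na(tr$auditory_onset)
      bad <- cued & abs(tr$visual_onset - tr$auditory_onset -
                          object@stimDuration) > 1e-9
      if (any(bad))
        msg <- c(msg, "cued trials must have visual_onset = auditory_onset + stimulus duration")
      rein <- !is.na(tr$reinforcement_onset)
      if (any(rein & abs(tr$reinforcement_onset - tr$visual_onset -
                           object@stimDuration) > 1e-9))
        msg <- c(msg, "reinforcement_onset must equal visual_onset + stimulus duration")
      if (any(tr$reinforcement == "reward" & tr$condition != "AaVa"))
        msg <- c(msg, "reward is only delivered on AaVa trials")
      if (any(tr$reinforcement == "airpuff" & tr$condition != "AbVb"))
        msg <- c(msg, "airpuff is only delivered on AbVb trials")
      if (any(tr$condition == "Vc" & !is.na(tr$auditory_onset)))
        msg <- c(msg, "Vc is never preceded by an auditory cue")
      if (any(tr$condition == "AbVa" & tr$day != 5L))
        msg <- c(msg, "AbVa probe trials occur on day 5 only")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Class of generative ground truth for synthetic experiments
#'
#' Parameterizes the synthetic-data generator: per-ROI stimulus tuning,
#' calcium-kernel time constants, noise, receptive-field centres and
#' optogenetic-influence weights, together with day-wise cue-driven
#' suppression factors and behavioural probabilities. Suppression acts
#' multiplicatively on the visual amplitude of the paired cued condition
#' only; the day-5 recombined cue (AbVa) uses the unsuppressed amplitude.
#'
#' @slot roi data.frame, one row per ROI (amplitudes in dF/F units, taus in
#'   seconds, `fmi_pre`/`fmi_post` signed influence weights).
#' @slot suppression data.frame with columns `day`, `reward`, `airpuff`;
#'   factors in `[0, 1]`.
#' @slot lickProb data.frame with columns `day`, `condition`, `prob`.
#' @slot running list: `baseline` (cm/s), `dip` (fractional speed reduction
#'   during stimuli), `noiseSd`, `noiseTau` (s).
#' @slot population `"v1_soma"` or `"auc_axon"`.
#' @slot misc list of scenario extras (e.g. `anesthetizedScale`).
#' @export
setClass("GroundTruth",
  representation(roi = "data.frame", suppression = "data.frame",
                 lickProb = "data.frame", running = "list",
                 population = "character", misc = "list"),
  validity = function(object) {
    r <- object@roi
    msg <- NULL
    ampCols <- grep("^(vis|aud)_amp_", colnames(r), value = TRUE)
    for (cc in ampCols)
      if (any(r[[cc]] < 0)) msg <- c(msg, paste(cc, "must be non-negative"))
    if (any(r$noise_sigma < 0)) msg <- c(msg, "noise_sigma must be >= 0")
    if (any(r$tau_rise <= 0) || any(r$tau_decay <= 0))
      msg <- c(msg, "kernel time constants must be positive")
    if (any(r$tau_decay <= r$tau_rise))
      msg <- c(msg, "tau_decay must exceed tau_rise")
    s <- object@suppression
    if (any(s$reward < 0 | s$reward > 1 | s$airpuff < 0 | s$airpuff > 1))
      msg <- c(msg, "suppression factors must lie in [0, 1]")
    if (nrow(object@lickProb) &&
        any(object@lickProb$prob < 0 | object@lickProb$prob > 1))
      msg <- c(msg, "lick probabilities must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Class of raw ROI fluorescence recordings
#'
#' ROI-by-frame matrix of raw fluorescence (arbitrary units), i.e. the mean
#' pixel value of each ROI per frame, plus the effective frame rate.
#'
#' @slot raw numeric matrix, ROIs in rows, frames in columns.
#' @slot frameRate effective frame rate (Hz).
#' @slot roiIds character ROI identifiers (rownames of `raw`).
#' @export
setClass("FluorescenceRecording",
  representation(raw = "matrix", frameRate = "numeric", roiIds = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive number")
    if (!all(is.finite(object@raw))) msg <- c(msg, "raw values must be finite")
    else if (any(object@raw < 0)) msg <- c(msg, "raw fluorescence must be non-negative")
    if (length(object@roiIds) != nrow(object@raw))
      msg <- c(msg, "one roiId per matrix row required")
    if (is.null(msg)) TRUE else msg
  })

#' Class of median-normalized dF/F trace sets
#'
#' dF/F is computed per ROI as `(F - median(F)) / median(F)`; the per-ROI
#' raw medians are retained so the normalization is reproducible. ROIs with
#' non-positive median are excluded upstream.
#'
#' @slot dff numeric matrix, ROI x frame, dimensionless.
#' @slot medians per-ROI median of the raw trace.
#' @slot frameRate effective frame rate (Hz).
#' @slot provenance list describing normalization/filter settings.
#' @export
setClass("DffTraceSet",
  representation(dff = "matrix", medians = "numeric", frameRate = "numeric",
                 provenance = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@medians) != nrow(object@dff))
      msg <- c(msg, "one median per ROI required")
    if (any(object@medians <= 0)) msg <- c(msg, "medians must be positive")
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Class of trial-aligned dF/F tensors
#'
#' ROI x trial x relative-frame block of dF/F aligned to a trial event.
#' Relative frame 0 is the frame at or immediately after the alignment
#' onset. Trials whose windows exceed the recording are dropped and logged.
#'
#' @slot values 3-d numeric array `[roi, trial, relative frame]`.
#' @slot relBins integer relative frame indices (third dimnames axis).
#' @slot trials data.frame of surviving trial metadata.
#' @slot alignTo the onset column used for alignment.
#' @slot frameRate effective frame rate (Hz).
#' @slot dropped data.frame logging dropped trials and reasons.
#' @export
setClass("TrialTensor",
  representation(values = "array", relBins = "integer", trials = "data.frame",
                 alignTo = "character", frameRate = "numeric",
                 dropped = "data.frame"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@values)
    if (length(d) != 3L) msg <- c(msg, "values must be a 3-d array")
    else {
      if (d[2L] != nrow(object@trials))
        msg <- c(msg, "trial axis must match trial metadata rows")
      if (d[3L] != length(object@relBins))
        msg <- c(msg, "frame axis must match relBins")
    }
    if (length(object@relBins) && any(diff(object@relBins) != 1L))
      msg <- c(msg, "relBins must be contiguous")
    if (is.null(msg)) TRUE else msg
  })

#' Class of per-trial scalar response tables
#'
#' Tidy per-(ROI, trial) baseline-subtracted windowed responses with
#' condition and day labels. The aggregation unit used for population
#' summaries (neurons/axons vs mice) is mandatory metadata.
#'
#' @slot table data.frame: `roi_id`, `trial_id`, `condition`, `day`,
#'   `response` (dF/F), plus optional event covariates (e.g. `pos_x`).
#' @slot aggregationUnit `"roi"` or `"mouse"`.
#' @slot window the [WindowSpec-class] used.
#' @export
setClass("ResponseTable",
  representation(table = "data.frame", aggregationUnit = "character",
                 window = "WindowSpec"),
  validity = function(object) {
    need <- c("roi_id", "trial_id", "condition", "day", "response")
    missing <- setdiff(need, colnames(object@table))
    if (length(missing))
      return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (!object@aggregationUnit %in% c("roi", "mouse"))
      return("aggregationUnit must be 'roi' or 'mouse'")
    TRUE
  })

#' Class of behavioral recordings
#'
#' Lick-sensor voltage and running-speed time series with their sample
#' rates, plus detected lick event times when available.
#'
#' @slot lickVoltage numeric voltage series.
#' @slot lickRate sample rate of `lickVoltage` (Hz).
#' @slot speed running speed series (cm/s, non-negative).
#' @slot speedRate sample rate of `speed` (Hz).
#' @slot lickEvents numeric lick event times (s), strictly increasing.
#' @export
setClass("BehaviorRecord",
  representation(lickVoltage = "numeric", lickRate = "numeric",
                 speed = "numeric", speedRate = "numeric",
                 lickEvents = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@speed < 0)) msg <- c(msg, "speeds must be non-negative")
    if (length(object@lickEvents) > 1L && any(diff(object@lickEvents) <= 0))
      msg <- c(msg, "lick event times must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Class of ROI pixel masks
#'
#' @slot pixels integer matrix (n x 2: row, col), 1-based pixel coordinates.
#' @slot dims frame dimensions `c(nrow, ncol)`.
#' @export
setClass("RoiMask",
  representation(pixels = "matrix", dims = "integer"),
  validity = function(object) {
    if (nrow(object@pixels) == 0L) return("mask must be non-empty")
    if (ncol(object@pixels) != 2L) return("pixels must be an n x 2 matrix")
    if (any(object@pixels < 1L) ||
        any(object@pixels[, 1L] > object@dims[1L]) ||
        any(object@pixels[, 2L] > object@dims[2L]))
      return("mask pixels must lie within frame bounds")
    TRUE
  })

#' Class of visual-space receptive-field maps
#'
#' Mean windowed response binned on a grid of visual-space positions
#' (corridor coordinate x elevation), with an s.e.m. companion map and the
#' peak-normalization constant when normalized. Empty cells are `NA`
#' (missing), never zero.
#'
#' @slot mean,sem,n matrices (ny x nx): cell mean, s.e.m., event count.
#' @slot xCenters,yCenters grid-cell centre coordinates.
#' @slot normConstant peak value used for normalization (`NA` if raw).
#' @export
setClass("ReceptiveFieldMap",
  representation(mean = "matrix", sem = "matrix", n = "matrix",
                 xCenters = "numeric", yCenters = "numeric",
                 normConstant = "numeric"),
  validity = function(object) {
    d <- dim(object@mean)
    if (!all(dim(object@sem) == d) || !all(dim(object@n) == d))
      return("mean, sem and n maps must share dimensions")
    if (d[2L] != length(object@xCenters) || d[1L] != length(object@yCenters))
      return("grid centres must match map dimensions")
    TRUE
  })

#' Class of response-difference-index results
#'
#' Per-ROI index `(uncued - cued) / normReference`, where the reference is
#' the day-1 population mean un-cued response, with the population test
#' against zero from the normality-gated dispatcher.
#'
#' @slot perRoi named per-ROI indices.
#' @slot mean,sem population mean and s.e.m. of the index.
#' @slot normReference normalization constant (day-1 mean un-cued response).
#' @slot test list: dispatcher output for the comparison to 0.
#' @export
setClass("ResponseDifferenceResult",
  representation(perRoi = "numeric", mean = "numeric", sem = "numeric",
                 normReference = "numeric", test = "list"),
  validity = function(object) {
    if (length(object@normReference) != 1L || object@normReference == 0)
      return("normReference must be a single non-zero number")
    TRUE
  })

#' Class of bin-by-bin test results
#'
#' Per-bin p-values from one-frame-bin tests between two aligned response
#' sets, with significance flags restricted to runs of at least
#' `minConsecutive` consecutive significant bins.
#'
#' @slot bins relative frame bins tested.
#' @slot pValues per-bin two-sided p-values.
#' @slot significant per-bin flags (TRUE only inside qualifying runs).
#' @slot runs data.frame of maximal qualifying runs (`start`, `end`, bins).
#' @slot alpha,minConsecutive test parameters.
#' @slot test character, the per-bin test used.
#' @export
setClass("BinwiseTestResult",
  representation(bins = "integer", pValues = "numeric", significant = "logical",
                 runs = "data.frame", alpha = "numeric",
                 minConsecutive = "integer", test = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@pValues) != length(object@bins) ||
        length(object@significant) != length(object@bins))
      msg <- c(msg, "pValues and flags must match bins")
    p <- object@pValues[!is.na(object@pValues)]
    if (any(p < 0 | p > 1)) msg <- c(msg, "p-values must lie in [0, 1]")
    if (nrow(object@runs) &&
        any(object@runs$end - object@runs$start + 1L < object@minConsecutive))
      msg <- c(msg, "flagged runs must have length >= minConsecutive")
    if (is.null(msg)) TRUE else msg
  })
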