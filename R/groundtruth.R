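#' @include AllClasses.R
NULL

.defaultLickProb <- function(days = 1:5) {
  # anticipatory licking grows with day for the cued-rewarded pair and
  # stays flat for everything else
  conds <- c("AaVa", "AbVb", "AbVa", "Va", "Vb", "Vc")
  probs <- rbind(
    AaVa = c(0.2, 0.3, 0.5, 0.7, 0.7),
    AbVb = rep(0.1, 5), AbVa = rep(0.2, 5),
    Va = rep(0.2, 5), Vb = rep(0.1, 5), Vc = rep(0.1, 5))
  do.call(rbind, lapply(days, function(d) data.frame(
    day = as.integer(d), condition = conds,
    prob = probs[conds, min(d, 5L)], stringsAsFactors = FALSE)))
}

#' Construct generative ground truth for a synthetic experiment
#'
#' Draws per-ROI stimulus tuning, calcium-kernel time constants, noise
#' levels, receptive-field centres and optogenetic-influence weights, and
#' sets the day-wise cue-driven suppression factors and behavioural
#' parameters that downstream analyses should recover.
#'
#' Populations: `"v1_soma"` is GCaMP6f-like (50 ms rise, 600 ms decay) with
#' purely visual tuning; `"auc_axon"` is slower (1.2 s decay) and carries
#' both auditory and retinotopic visual amplitudes.
#'
#' Scenarios:
#' \describe{
#'   \item{default}{Rewarded-pairing suppression grows over days
#'     (0, 0.05, 0.15, 0.3, 0.3); air-puff pairing suppression is weaker and
#'     flat (0.1). Anticipatory licking grows with day for AaVa only.}
#'   \item{null}{All suppression factors 0 and flat behaviour.}
#'   \item{pre_learning}{Optogenetic influence weights independent of visual
#'     tuning (both pre and post).}
#'   \item{post_learning}{Post-conditioning influence weights negatively
#'     coupled to the Va visual amplitude, so opto-inhibited ROIs are
#'     enriched for Va responsiveness; Vc tuning stays independent.}
#' }
#'
#' @param nRoi Number of ROIs.
#' @param population `"v1_soma"` or `"auc_axon"`.
#' @param scenario Scenario name (see Details).
#' @param seed Integer seed.
#' @param suppression Optional length-5 numeric overriding the rewarded
#'   pairing's day-wise suppression factors.
#' @param noiseSigma dF/F noise s.d. per frame (default 0.1).
#' @param lickProb Optional data.frame (`day`, `condition`, `prob`)
#'   overriding anticipatory-lick probabilities.
#' @param visualAmpMean Mean visual response amplitude (dF/F).
#' @param responsiveFraction Fraction of ROIs given non-zero visual tuning.
#' @return A [GroundTruth-class].
#' @export
makeGroundTruth <- function(nRoi = 200,
                            population = c("v1_soma", "auc_axon"),
                            scenario = c("default", "null", "pre_learning",
                                         "post_learning", "no_reinforcement"),
                            seed = 1,
                            suppression = NULL,
                            noiseSigma = 0.1,
                            lickProb = NULL,
                            visualAmpMean = 0.3,
                            responsiveFraction = 1) {
  population <- match.arg(population)
  scenario <- match.arg(scenario)
  if (noiseSigma < 0) .configError("noiseSigma must be >= 0")
  if (responsiveFraction < 0 || responsiveFraction > 1)
    .configError("responsiveFraction must lie in [0, 1]")
  set.seed(as.integer(seed))

  responsive <- stats::runif(nRoi) < responsiveFraction
  drawAmp <- function(mean) {
    a <- stats::rgamma(nRoi, shape = 4, scale = mean / 4)
    a * responsive
  }
  visA <- drawAmp(visualAmpMean)
  visB <- drawAmp(visualAmpMean)
  visC <- drawAmp(visualAmpMean)
  if (population == "v1_soma") {
    audA <- audB <- numeric(nRoi)     # somatic baseline window nets out
    tauR <- rep(0.05, nRoi); tauD <- rep(0.6, nRoi)
  } else {
    audA <- drawAmp(visualAmpMean / 2)
    audB <- drawAmp(visualAmpMean / 2)
    tauR <- rep(0.05, nRoi); tauD <- rep(1.2, nRoi)
  }

  fmiPre <- stats::rnorm(nRoi, 0, 0.08)
  fmiPost <- switch(scenario,
    post_learning = -0.06 * as.numeric(scale(visA)) + stats::rnorm(nRoi, 0, 0.05),
    stats::rnorm(nRoi, 0, 0.08))

  roi <- data.frame(
    roi_id = sprintf("roi%04d", seq_len(nRoi)),
    vis_amp_a = visA, vis_amp_b = visB, vis_amp_c = visC,
    aud_amp_a = audA, aud_amp_b = audB,
    rf_x = stats::runif(nRoi), rf_y = stats::runif(nRoi),
    rf_sigma = rep(0.12, nRoi),
    fmi_pre = fmiPre, fmi_post = fmiPost,
    noise_sigma = rep(noiseSigma, nRoi),
    tau_rise = tauR, tau_decay = tauD,
    baseline_f0 = stats::runif(nRoi, 80, 120),
    stringsAsFactors = FALSE)

  reward <- if (!is.null(suppression)) rep_len(suppression, 5)
            else switch(scenario,
              null = rep(0, 5),
              no_reinforcement = rep(0, 5),
              c(0, 0.05, 0.15, 0.3, 0.3))
  airpuff <- switch(scenario, null = rep(0, 5), no_reinforcement = rep(0, 5),
                    rep(0.1, 5))
  supp <- data.frame(day = 1:5, reward = reward, airpuff = airpuff)

  lp <- if (!is.null(lickProb)) lickProb
        else if (scenario %in% c("null", "no_reinforcement")) {
          d <- .defaultLickProb(); d$prob <- 0.1; d
        } else .defaultLickProb()

  methods::new("GroundTruth", roi = roi, suppression = supp, lickProb = lp,
    running = list(baseline = 10, dip = 0.3, noiseSd = 0.08, noiseTau = 1),
    population = population,
    misc = list(scenario = scenario, anesthetizedScale = 0.1))
}

#' Serialize ground truth to a JSON sidecar
#' @param truth A [GroundTruth-class].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(
    population = truth@population, roi = truth@roi,
    suppression = truth@suppression, lickProb = truth@lickProb,
    running = truth@running, misc = truth@misc),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("GroundTruth", roi = as.data.frame(x$roi),
    suppression = as.data.frame(x$suppression),
    lickProb = as.data.frame(x$lickProb), running = as.list(x$running),
    population = x$population, misc = as.list(x$misc))
}
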