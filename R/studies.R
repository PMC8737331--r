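#' @include AllClasses.R pipeline.R
NULL

#' Type-I error control study on no-effect simulations
#'
#' Draws no-effect replicates from the generative model's implied response
#' distributions and measures (a) the rejection rate of the one-sample
#' test on the response difference index and (b) the rate of spurious
#' >= `minConsecutive`-bin significance runs in the bin-by-bin paired
#' comparison. Per-trial windowed responses are Gaussian around the
#' kernel-window gain times the ROI amplitude with the analytically known
#' window noise; per-bin values carry the shared-baseline covariance
#' induced by baseline subtraction. An independent brute-force Monte-Carlo
#' of the same null model (plain-loop t statistics) provides the oracle
#' flag rate, and the exact independent-bin run probability is computed by
#' dynamic programming as a reference.
#'
#' @param nReplicates Number of null replicates.
#' @param nRoi ROIs per replicate.
#' @param trialsPerCondition Trials per condition.
#' @param noiseSigma Generative per-frame dF/F noise s.d.
#' @param alpha Test level.
#' @param minConsecutive Run length for binwise flagging.
#' @param seed Integer seed.
#' @param oracleReplicates Replicates for the brute-force oracle.
#' @return List: `indexRejectionRate`, `binwiseFlagRate`,
#'   `oracleFlagRate`, `dpIndependentRunProbability`, `mcse` (per rate),
#'   and the study sizes.
#' @export
nullControlStudy <- function(nReplicates = 1000, nRoi = 200,
                             trialsPerCondition = 40, noiseSigma = 0.1,
                             alpha = 0.05, minConsecutive = 3, seed = 1,
                             oracleReplicates = 2 * nReplicates) {
  w <- windowSpec(15)
  g <- windowGain(w)
  nB <- length(responseBins(w))
  nBase <- length(baselineBins(w))
  sTrial <- noiseSigma * sqrt(1 / nB + 1 / nBase)   # per-trial scalar noise
  sBin <- noiseSigma / sqrt(trialsPerCondition)     # per-bin trial-avg noise
  sBeta <- noiseSigma / sqrt(nBase * trialsPerCondition)  # shared baseline

  set.seed(childSeed(seed, "null_index"))
  reject <- logical(nReplicates)
  flagged <- logical(nReplicates)
  for (r in seq_len(nReplicates)) {
    amp <- stats::rgamma(nRoi, shape = 4, scale = 0.075)
    mu <- g * amp
    cued <- mu + stats::rnorm(nRoi, 0, sTrial / sqrt(trialsPerCondition))
    uncued <- mu + stats::rnorm(nRoi, 0, sTrial / sqrt(trialsPerCondition))
    res <- responseDifferenceIndex(cued, uncued, mean(uncued))
    reject[r] <- res@test$p.value < alpha

    A <- matrix(stats::rnorm(nRoi * nB, 0, sBin), nRoi) -
      stats::rnorm(nRoi, 0, sBeta)
    B <- matrix(stats::rnorm(nRoi * nB, 0, sBin), nRoi) -
      stats::rnorm(nRoi, 0, sBeta)
    bw <- binwiseDifferenceTest(A, B, alpha = alpha,
                                minConsecutive = minConsecutive,
                                paired = TRUE)
    flagged[r] <- nrow(bw@runs) > 0L
  }

  # brute-force oracle: same null model, naive t statistics and run scan
  set.seed(childSeed(seed, "null_oracle"))
  hits <- logical(oracleReplicates)
  for (r in seq_len(oracleReplicates)) {
    A <- matrix(stats::rnorm(nRoi * nB, 0, sBin), nRoi) -
      stats::rnorm(nRoi, 0, sBeta)
    B <- matrix(stats::rnorm(nRoi * nB, 0, sBin), nRoi) -
      stats::rnorm(nRoi, 0, sBeta)
    run <- 0L; hit <- FALSE
    for (b in seq_len(nB)) {
      d <- A[, b] - B[, b]
      tt <- mean(d) / stats::sd(d) * sqrt(nRoi)
      p <- 2 * stats::pt(-abs(tt), nRoi - 1)
      run <- if (p < alpha) run + 1L else 0L
      if (run >= minConsecutive) { hit <- TRUE; break }
    }
    hits[r] <- hit
  }

  list(indexRejectionRate = mean(reject),
       binwiseFlagRate = mean(flagged),
       oracleFlagRate = mean(hits),
       dpIndependentRunProbability =
         .runProbabilityDP(nB, alpha, minConsecutive),
       mcse = c(index = sqrt(alpha * (1 - alpha) / nReplicates),
                binwise = stats::sd(flagged) / sqrt(nReplicates),
                oracle = stats::sd(hits) / sqrt(oracleReplicates)),
       nReplicates = nReplicates, nRoi = nRoi, alpha = alpha)
}

# exact P(>= one run of m successes in n independent Bernoulli(p) trials)
.runProbabilityDP <- function(n, p, m) {
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

#' Optogenetic-influence selectivity recovery study
#'
#' Per replicate: simulate an influence-mapping session, classify ROIs as
#' inhibited/excited by their opto response, simulate a visual session with
#' un-cued Va and control Vc trials, and compare the groups' visual
#' responses with both the windowed normality-gated dispatcher (unpaired,
#' the calibrated decision reported as `vaDetected`/`vcDetected`) and the
#' bin-by-bin trace comparison with the consecutive-bin rule
#' (`vaBinwise`/`vcBinwise`). In the post-learning scenario inhibited ROIs
#' are enriched for Va responsiveness, so a Va (but no Vc) difference
#' should be reported; in the pre-learning scenario influence weights are
#' independent of tuning and neither should exceed the test level.
#'
#' @param nReplicates Replicates.
#' @param nRoi ROIs per replicate (the influence-mapping population).
#' @param scenario `"post_learning"` or `"pre_learning"`.
#' @param trialsPerCondition Visual trials per condition.
#' @param optoTrials Opto stimulation trials.
#' @param alpha Test level.
#' @param seed Integer seed.
#' @return data.frame, one row per replicate: `vaDetected`, `vcDetected`,
#'   `vaBinwise`, `vcBinwise`, `nInhibited`.
#' @export
fmiSelectivityStudy <- function(nReplicates = 50, nRoi = 563,
                                scenario = c("post_learning", "pre_learning"),
                                trialsPerCondition = 20, optoTrials = 20,
                                alpha = 0.05, seed = 1) {
  scenario <- match.arg(scenario)
  w <- windowSpec(15)
  out <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    sd0 <- childSeed(seed, sprintf("fmi_%s_%d", scenario, r))
    truth <- makeGroundTruth(nRoi, "v1_soma", scenario,
                             seed = childSeed(sd0, "truth"))
    op <- simulateOptoSession(truth, nTrials = optoTrials, phase = "post",
                              includeSham = FALSE,
                              seed = childSeed(sd0, "opto"))
    rto <- quantifyResponse(
      alignTrials(computeDff(op$recording), op$schedule, "opto_onset"), w)
    labels <- classifyFmi(roiMeans(rto, "opto"))

    cfg <- scheduleConfig(days = 4, trialsPerDay = 2 * trialsPerCondition)
    cfg$uncuedFraction[] <- 1
    cfg$vcFractionOfUncued <- 0.5
    cfg$uncuedStimuli <- "Va"
    sched <- makeTrialSchedule(cfg, seed = childSeed(sd0, "schedule"))
    sim <- simulateNeuralTraces(sched, truth, 15,
                                seed = childSeed(sd0, "neural"))
    tt <- alignTrials(computeDff(sim$recording), sched, "visual_onset")
    rt <- quantifyResponse(tt, w)

    one <- function(cond) {
      m <- roiMeans(rt, cond)
      ht <- dispatchTest(m[labels == "inhibited"], m[labels == "excited"],
                         design = "unpaired")
      sel <- trialInfo(tt)$condition == cond
      sub <- methods::new("TrialTensor",
        values = tt@values[, sel, , drop = FALSE], relBins = relBins(tt),
        trials = trialInfo(tt)[sel, , drop = FALSE], alignTo = tt@alignTo,
        frameRate = frameRate(tt), dropped = tt@dropped)
      cmp <- compareGroupResponses(labels, sub, w, alpha = alpha)
      c(detected = ht$p.value < alpha, binwise = nrow(cmp$binwise@runs) > 0L)
    }
    va <- one("Va"); vc <- one("Vc")
    out[[r]] <- data.frame(vaDetected = va[["detected"]],
                           vcDetected = vc[["detected"]],
                           vaBinwise = va[["binwise"]],
                           vcBinwise = vc[["binwise"]],
                           nInhibited = sum(labels == "inhibited"))
  }
  do.call(rbind, out)
}

#' Receptive-field peak recovery study
#'
#' Simulates axons with Gaussian receptive fields, maps each axon's
#' responses over the visual-space grid through the full trace pipeline,
#' and scores the fraction of axons whose map peak falls within one grid
#' step of the generative centre.
#'
#' @param nAxons Number of simulated axons.
#' @param grid A [rfGrid()].
#' @param nRepeats Stimulus presentations per grid position.
#' @param noiseSigma Generative dF/F noise s.d.
#' @param seed Integer seed.
#' @return List: `hitFraction`, `hits` (per axon), `nAxons`.
#' @export
rfRecoveryStudy <- function(nAxons = 100, grid = rfGrid(), nRepeats = 5,
                            noiseSigma = 0.1, seed = 1) {
  sched <- makeRfSchedule(grid, nRepeats = nRepeats,
                          seed = childSeed(seed, "rf_schedule"))
  truth <- makeGroundTruth(nAxons, "auc_axon",
                           seed = childSeed(seed, "rf_truth"),
                           noiseSigma = noiseSigma)
  sim <- simulateNeuralTraces(sched, truth, 15,
                              seed = childSeed(seed, "rf_neural"))
  rt <- quantifyResponse(
    alignTrials(computeDff(sim$recording), sched, "visual_onset"),
    windowSpec(15))
  tab <- responses(rt)
  stepX <- diff(grid$xlim) / grid$nx
  stepY <- diff(grid$ylim) / grid$ny
  hits <- vapply(unique(tab$roi_id), function(id) {
    sub <- tab[tab$roi_id == id, ]
    pk <- peakLocation(mapVisualSpace(sub$response,
                                      sub[, c("pos_x", "pos_y")], grid))
    i <- match(id, truth@roi$roi_id)
    abs(pk$x - truth@roi$rf_x[i]) <= 1.5 * stepX &&
      abs(pk$y - truth@roi$rf_y[i]) <= 1.5 * stepY
  }, logical(1))
  list(hitFraction = mean(hits), hits = hits, nAxons = nAxons)
}

#' Anticipatory-licking recovery study
#'
#' Simulates a cohort of mice through the conditioning paradigm (behaviour
#' only), detects licks from the voltage traces, and compares recovered
#' per-(condition, day) lick-trial fractions with the generative
#' probabilities; per day, cued vs un-cued anticipatory licking is
#' compared across mice with the paired dispatcher.
#'
#' @param nMice Number of simulated mice.
#' @param days Conditioning days.
#' @param trialsPerDay Trials per daily session.
#' @param seed Integer seed.
#' @return List: `fractions` (condition x day: recovered, truth, n),
#'   `tests` (per day: p-value of cued vs un-cued across mice),
#'   `perMouse`.
#' @export
behaviorRecoveryStudy <- function(nMice = 10, days = 1:4, trialsPerDay = 120,
                                  seed = 1) {
  truth <- makeGroundTruth(2, seed = childSeed(seed, "behavior_truth"))
  trials <- vector("list", nMice)
  for (m in seq_len(nMice)) {
    cfg <- scheduleConfig(days = days, trialsPerDay = trialsPerDay)
    cfg$mouse <- sprintf("m%02d", m)
    sched <- makeTrialSchedule(cfg, seed = childSeed(seed, paste0("sched", m)))
    beh <- simulateBehavior(sched, truth, 100,
                            seed = childSeed(seed, paste0("beh", m)))
    ev <- detectLicks(beh@lickVoltage, beh@lickRate)
    trials[[m]] <- anticipatoryLicking(ev, sched)$trials
  }
  trials <- do.call(rbind, trials)
  lp <- truth@lickProb
  fr <- stats::aggregate(any_lick ~ condition + day, data = trials, FUN = mean)
  names(fr)[names(fr) == "any_lick"] <- "recovered"
  fr$n <- stats::aggregate(any_lick ~ condition + day, data = trials,
                           FUN = length)$any_lick
  fr$truth <- mapply(function(cc, d) {
    hit <- lp$condition == cc & lp$day == min(d, max(lp$day))
    if (any(hit)) lp$prob[which(hit)[1L]] else NA_real_
  }, fr$condition, fr$day)

  perMouse <- stats::aggregate(any_lick ~ condition + day + mouse,
                               data = trials, FUN = mean)
  tests <- do.call(rbind, lapply(sort(unique(perMouse$day)), function(d) {
    a <- perMouse$any_lick[perMouse$condition == "AaVa" & perMouse$day == d]
    v <- perMouse$any_lick[perMouse$condition == "Va" & perMouse$day == d]
    mice <- sort(unique(perMouse$mouse))
    am <- perMouse[perMouse$condition == "AaVa" & perMouse$day == d, ]
    vm <- perMouse[perMouse$condition == "Va" & perMouse$day == d, ]
    a <- am$any_lick[match(mice, am$mouse)]
    v <- vm$any_lick[match(mice, vm$mouse)]
    ok <- !is.na(a) & !is.na(v)
    ht <- dispatchTest(a[ok], v[ok], design = "paired")
    data.frame(day = d, p = ht$p.value, test = ht$test,
               meanCued = mean(a[ok]), meanUncued = mean(v[ok]))
  }))
  list(fractions = fr, tests = tests, perMouse = perMouse)
}
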