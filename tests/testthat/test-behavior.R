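test_that("lick detection registers upward threshold crossings only", {
  # flat sub-threshold voltage -> no events
  expect_length(detectLicks(rep(1, 1000), 100), 0L)
  # one square pulse -> exactly one event at the rising edge
  v <- rep(0, 1000); v[501:520] <- 5
  ev <- detectLicks(v, 100, threshold = 2.5)
  expect_equal(ev, 500 / 100)
  # two pulses inside the refractory period merge into one event
  v2 <- rep(0, 1000); v2[101:102] <- 5; v2[104:105] <- 5
  expect_length(detectLicks(v2, 100, refractoryMs = 50), 1L)
  expect_length(detectLicks(v2, 100, refractoryMs = 0), 2L)
  expect_error(detectLicks(c(1, NA, 2), 100), "finite")
})

test_that("synthetic lick events are recovered exactly from clean pulses", {
  sched <- makeTrialSchedule(scheduleConfig(days = 4, trialsPerDay = 60), 2)
  truth <- makeGroundTruth(5, seed = 1)
  beh <- simulateBehavior(sched, truth, sampleRate = 100, seed = 9)
  ev <- detectLicks(beh@lickVoltage, beh@lickRate)
  expect_identical(length(ev), length(beh@lickEvents))
  # detected at the sample grid: within one sample of the generative time
  expect_true(all(abs(ev - beh@lickEvents) <= 1 / 100 + 1e-9))
})

test_that("anticipatory licking fractions recover generative probabilities", {
  # 10 mice, day 4: cued 0.7 vs un-cued 0.2
  perMouse <- lapply(1:10, function(m) {
    cfg <- scheduleConfig(days = 4, trialsPerDay = 60)
    cfg$mouse <- paste0("m", m)
    sched <- makeTrialSchedule(cfg, seed = 100 + m)
    truth <- makeGroundTruth(2, seed = 1)
    beh <- simulateBehavior(sched, truth, 100, seed = 200 + m)
    anticipatoryLicking(detectLicks(beh@lickVoltage, 100), sched)$trials
  })
  trials <- do.call(rbind, perMouse)
  fCued <- mean(trials$any_lick[trials$condition == "AaVa"])
  fUncued <- mean(trials$any_lick[trials$condition == "Va"])
  nC <- sum(trials$condition == "AaVa"); nU <- sum(trials$condition == "Va")
  expect_lt(abs(fCued - 0.7), 3.5 * sqrt(0.7 * 0.3 / nC))
  expect_lt(abs(fUncued - 0.2), 3.5 * sqrt(0.2 * 0.8 / nU))
  # zero probability -> zero events
  t0 <- makeGroundTruth(2, scenario = "default", seed = 1,
                        lickProb = within(crossmodal:::.defaultLickProb(),
                                          prob <- 0))
  sched <- makeTrialSchedule(scheduleConfig(days = 1, trialsPerDay = 30), 1)
  expect_length(simulateBehavior(sched, t0, 100, seed = 1)@lickEvents, 0L)
})

test_that("lick/no-lick splits partition trials exhaustively", {
  relBins <- -12:16
  v <- array(rnorm(2 * 6 * length(relBins)), c(2, 6, length(relBins)))
  tt <- toyTensor(v, relBins)
  lickTable <- data.frame(trial_id = 1:6, any_lick = rep(c(TRUE, FALSE), 3))
  sp <- splitByLicking(tt, lickTable)
  expect_identical(unname(sp$sizes), c(3L, 3L))
  expect_identical(nTrials(sp$lick) + nTrials(sp$noLick), nTrials(tt))
  expect_setequal(c(trialInfo(sp$lick)$trial_id, trialInfo(sp$noLick)$trial_id),
                  1:6)
  # all-lick case: empty partition triggers a warning
  allLick <- data.frame(trial_id = 1:6, any_lick = TRUE)
  expect_warning(sp2 <- splitByLicking(tt, allLick), "no no-lick")
  expect_null(sp2$noLick)
})

test_that("speed matching reproduces the hand-traced removal sequence", {
  res <- speedMatchTrials(c(10, 2, 2), c(1, 1, 9))
  expect_identical(res$iterations, 1L)
  expect_identical(res$initiallyHigher, "A")
  expect_identical(res$keptA, 2:3)          # the 10 was removed
  expect_identical(res$keptB, 2:3)          # the first 1 was removed
  expect_equal(res$log$mean_higher, 2)
  expect_equal(res$log$mean_lower, 5)
})

test_that("speed matching with tied means designates A higher and removes nothing", {
  res <- speedMatchTrials(c(2, 2), c(1, 3))   # equal means: tie-break to A
  expect_identical(res$iterations, 0L)
  expect_identical(res$initiallyHigher, "A")
  expect_identical(res$keptA, 1:2)
  expect_identical(res$keptB, 1:2)
})

test_that("speed matching flips the mean ordering and removes equal counts", {
  set.seed(42)
  nFlip <- 0; nDone <- 0
  for (rep in 1:200) {
    a <- runif(sample(5:30, 1), 0, 10) + runif(1, 0, 3)  # shifted family
    b <- runif(sample(5:30, 1), 0, 10)
    res <- tryCatch(speedMatchTrials(a, b), error = function(e) NULL)
    if (is.null(res)) next
    nDone <- nDone + 1
    hi <- if (res$initiallyHigher == "A") a else b
    lo <- if (res$initiallyHigher == "A") b else a
    keptHi <- if (res$initiallyHigher == "A") res$keptA else res$keptB
    keptLo <- if (res$initiallyHigher == "A") res$keptB else res$keptA
    if (mean(hi[keptHi]) < mean(lo[keptLo])) nFlip <- nFlip + 1
    # equal removals from both groups; bounded iteration count
    expect_identical(length(a) - length(res$keptA),
                     length(b) - length(res$keptB))
    expect_lte(res$iterations, min(length(a), length(b)))
    # membership only: retained values are untouched
    expect_identical(a[res$keptA], a[sort(res$keptA)])
  }
  expect_gt(nDone, 100)
  expect_identical(nFlip, nDone)   # ordering flipped in 100% of completions
})

test_that("speed matching errors when a group is exhausted", {
  expect_error(speedMatchTrials(c(10, 10, 10), c(1, 1, 1)), "exhausted")
})

test_that("running quantification averages the trial window", {
  sched <- gridSchedule(c(20, 40), isi = c(10, 20))
  qr <- quantifyRunning(rep(7, 5000), 100, sched)
  expect_equal(qr$trials$mean_speed, c(7, 7))
  expect_equal(quantifyRunning(rep(0, 5000), 100, sched)$trials$mean_speed,
               c(0, 0))
  # trials outside coverage are dropped and reported
  qr2 <- quantifyRunning(rep(7, 2500), 100, sched)
  expect_identical(qr2$dropped, 2L)
})

test_that("generative running dips appear at the configured magnitude", {
  sched <- makeTrialSchedule(scheduleConfig(days = 1, trialsPerDay = 60), 3)
  truth <- makeGroundTruth(2, seed = 1)   # 30% dip, baseline 10 cm/s
  beh <- simulateBehavior(sched, truth, 100, seed = 4)
  qr <- quantifyRunning(beh@speed, 100, sched, window_s = c(0, 1))
  stimMean <- mean(qr$trials$mean_speed)
  expect_lt(abs(stimMean - 0.7 * 10), 0.6)   # ~0.7 x baseline
})
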