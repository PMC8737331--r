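test_that("generators are pure functions of (config, seed)", {
  truth <- makeGroundTruth(10, seed = 5)
  expect_identical(makeGroundTruth(10, seed = 5), truth)
  sched <- makeTrialSchedule(scheduleConfig(days = 1, trialsPerDay = 20), 2)
  s1 <- simulateNeuralTraces(sched, truth, 15, seed = 3)
  s2 <- simulateNeuralTraces(sched, truth, 15, seed = 3)
  expect_identical(rawTrace(s1$recording), rawTrace(s2$recording))
  s3 <- simulateNeuralTraces(sched, truth, 15, seed = 4)
  expect_false(identical(rawTrace(s1$recording), rawTrace(s3$recording)))
  b1 <- simulateBehavior(sched, truth, 100, seed = 6)
  b2 <- simulateBehavior(sched, truth, 100, seed = 6)
  expect_identical(b1@speed, b2@speed)
  # named child streams are distinct and below the 32-bit integer ceiling
  expect_false(childSeed(1, "neural") == childSeed(1, "behavior"))
  expect_lt(childSeed(.Machine$integer.max, "opto"), 2^31)
})

test_that("zero suppression makes cued and un-cued visual responses equal", {
  truth <- makeGroundTruth(150, "v1_soma", seed = 2, suppression = rep(0, 5))
  cfg <- scheduleConfig(days = 4, trialsPerDay = 80)
  cfg$cuedStimuli <- "AaVa"; cfg$uncuedStimuli <- "Va"
  cfg$uncuedFraction[] <- 0.5; cfg$vcFractionOfUncued <- 0
  sched <- makeTrialSchedule(cfg, seed = 3)
  sim <- simulateNeuralTraces(sched, truth, 15, seed = 4)
  rt <- quantifyResponse(
    alignTrials(computeDff(sim$recording), sched, "visual_onset"),
    windowSpec(15))
  mCued <- mean(roiMeans(rt, "AaVa"))
  mUncued <- mean(roiMeans(rt, "Va"))
  expect_lt(abs(mCued - mUncued) / mUncued, 0.05)
})

test_that("estimated index increases monotonically with generative suppression", {
  grid <- c(0, 0.15, 0.3)
  est <- vapply(seq_along(grid), function(i) {
    mean(vapply(1:3, function(r)
      crossmodal:::.estimateIndexOnce(grid[i], 150, 25,
                                      seed = 1000 * i + r), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_lt(max(abs(est - grid)), 0.08)
})

test_that("negative amplitudes in ground truth are rejected", {
  truth <- makeGroundTruth(5, seed = 1)
  truth@roi$vis_amp_a[1] <- -0.2
  expect_error(methods::validObject(truth), "non-negative")
  sched <- makeTrialSchedule(scheduleConfig(days = 1, trialsPerDay = 5), 1)
  expect_error(simulateNeuralTraces(sched, truth, 15, seed = 1))
})

test_that("opto sessions reflect influence weights; sham is uncorrelated", {
  truth <- makeGroundTruth(120, "v1_soma", "post_learning", seed = 9)
  ses <- simulateOptoSession(truth, nTrials = 25, phase = "post", seed = 3)
  tt <- alignTrials(computeDff(ses$recording), ses$schedule, "opto_onset")
  rt <- quantifyResponse(tt, windowSpec(15))
  opto <- roiMeans(rt, "opto")
  sham <- roiMeans(rt, "sham")
  g <- windowGain(windowSpec(15))
  # recovered opto response tracks the generative influence weight
  expect_gt(populationCorrelation(opto, truth@roi$fmi_post)$r, 0.9)
  expect_lt(max(abs(unname(opto) - truth@roi$fmi_post * g)), 0.1)
  # sham response carries no information about the influence weight
  expect_lt(abs(populationCorrelation(sham, truth@roi$fmi_post)$r), 0.25)
  expect_lt(abs(populationCorrelation(opto, sham)$r), 0.25)
  # all-zero influence weights: population mean opto response ~ 0
  t0 <- makeGroundTruth(80, seed = 4)
  t0@roi$fmi_pre[] <- 0
  ses0 <- simulateOptoSession(t0, nTrials = 20, phase = "pre", seed = 5)
  rt0 <- quantifyResponse(
    alignTrials(computeDff(ses0$recording), ses0$schedule, "opto_onset"),
    windowSpec(15))
  expect_lt(abs(mean(roiMeans(rt0, "opto"))), 0.02)
  expect_error(simulateOptoSession(truth, nTrials = 1), ">= 2")
})
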