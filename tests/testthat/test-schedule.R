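test_that("schedules satisfy timing and composition invariants", {
  cfg <- scheduleConfig(days = 1:5, trialsPerDay = 100)
  sched <- makeTrialSchedule(cfg, seed = 7)
  tr <- trialInfo(sched)

  # cued trials: 1-s auditory immediately followed by the visual stimulus
  cued <- !is.na(tr$auditory_onset)
  expect_true(all(abs(tr$visual_onset[cued] - tr$auditory_onset[cued] - 1) < 1e-9))
  rein <- !is.na(tr$reinforcement_onset)
  expect_true(all(abs(tr$reinforcement_onset[rein] - tr$visual_onset[rein] - 1) < 1e-9))
  expect_true(all(tr$reinforcement[tr$condition == "AaVa"] == "reward"))
  expect_true(all(tr$reinforcement[tr$condition == "AbVb"] == "airpuff"))

  # ISIs within bounds: gap between one trial's last event end and the next start
  for (d in 1:5) {
    td <- tr[tr$day == d, ]
    start <- ifelse(is.na(td$auditory_onset), td$visual_onset, td$auditory_onset)
    end <- td$visual_onset + 1 +
      ifelse(td$reinforcement == "none", 0, 1)
    isi <- start[-1] - end[-nrow(td)]
    expect_true(all(isi >= 4 - 1e-9 & isi <= 12 + 1e-9))
  }

  # the recombined probe appears on day 5 only
  expect_true(all(tr$day[tr$condition == "AbVa"] == 5L))
  expect_gt(sum(tr$condition == "AbVa"), 0L)
  # Vc is never cued
  expect_true(all(is.na(tr$auditory_onset[tr$condition == "Vc"])))
})

test_that("realized condition counts match requested fractions within binomial bounds", {
  cfg <- scheduleConfig(days = 1, trialsPerDay = 100)
  tr <- trialInfo(makeTrialSchedule(cfg, seed = 7))
  nUncued <- sum(tr$condition %in% c("Va", "Vb", "Vc"))
  # 3.5 sd binomial envelope around 25 of 100
  expect_lt(abs(nUncued - 25), 3.5 * sqrt(100 * 0.25 * 0.75))

  # larger sample: tighter relative check, plus day-5 probe fraction
  cfg5 <- scheduleConfig(days = 5, trialsPerDay = 800)
  tr5 <- trialInfo(makeTrialSchedule(cfg5, seed = 11))
  cued5 <- tr5$condition %in% c("AaVa", "AbVb", "AbVa")
  fAbVa <- sum(tr5$condition == "AbVa") / sum(cued5)
  expect_lt(abs(fAbVa - 0.14), 3.5 * sqrt(0.14 * 0.86 / sum(cued5)))
})

test_that("schedule generation is deterministic in (config, seed)", {
  cfg <- scheduleConfig(days = 1:2, trialsPerDay = 30)
  expect_identical(makeTrialSchedule(cfg, seed = 3),
                   makeTrialSchedule(cfg, seed = 3))
  s1 <- makeTrialSchedule(cfg, seed = 3)
  s2 <- makeTrialSchedule(cfg, seed = 4)
  expect_false(identical(trialInfo(s1)$visual_onset,
                         trialInfo(s2)$visual_onset))
})

test_that("invalid scheduling configurations are rejected", {
  cfg <- scheduleConfig()
  cfg$uncuedFraction[1] <- 1.2
  expect_error(makeTrialSchedule(cfg, 1), "fraction")
  cfg2 <- scheduleConfig()
  cfg2$isiBounds <- c(12, 4)
  expect_error(makeTrialSchedule(cfg2, 1), "ISI")
})

test_that("schedules round-trip through CSV", {
  sched <- makeTrialSchedule(scheduleConfig(days = 1, trialsPerDay = 20), 5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrialSchedule(sched, path)
  back <- readTrialSchedule(path)
  expect_equal(trialInfo(back)$visual_onset, trialInfo(sched)$visual_onset)
  expect_identical(trialInfo(back)$condition, trialInfo(sched)$condition)
})
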