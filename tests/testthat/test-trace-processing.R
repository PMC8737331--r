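test_that("dF/F follows the median-normalization formula", {
  expect_equal(unname(dff(computeDff(toyRecording(c(1, 1, 1, 3))))[1, ]),
               c(0, 0, 0, 2))
  # constant trace maps to all zeros
  expect_true(all(dff(computeDff(toyRecording(rep(5, 10)))) == 0))
  # one frame at twice the median peaks at exactly 1, whatever the scale
  for (m in c(0.5, 3, 200)) {
    r <- toyRecording(c(rep(m, 9), 2 * m))
    expect_equal(max(dff(computeDff(r))), 1)
  }
})

test_that("dF/F is invariant to raw fluorescence scale", {
  set.seed(1)
  raw <- matrix(abs(rnorm(300, 100, 10)), 3)
  r1 <- toyRecording(raw)
  r2 <- toyRecording(raw * 7.3)
  expect_equal(dff(computeDff(r1)), dff(computeDff(r2)), tolerance = 1e-12)
})

test_that("ROIs with non-positive median are excluded with a log entry", {
  raw <- rbind(rep(0, 6), c(1, 1, 1, 2, 2, 2))
  expect_message(d <- computeDff(toyRecording(raw)), "excluded")
  expect_identical(nrow(dff(d)), 1L)
  expect_identical(d@provenance$excluded, "roi0001")
  expect_error(suppressMessages(computeDff(toyRecording(rep(0, 6)))))
})

test_that("mean-pixel trace extraction is exact", {
  # uniform frame of value 7 -> trace constantly 7
  movie <- array(7, c(4, 4, 5))
  m <- rectMask(1:2, 1:2, c(4, 4))
  expect_true(all(rawTrace(extractRoiTraces(movie, list(m))) == 7))
  # 2x2 mask over pixels 1..4 -> mean 2.5
  movie2 <- array(0, c(2, 2, 1)); movie2[, , 1] <- matrix(1:4, 2)
  expect_equal(unname(rawTrace(extractRoiTraces(
    movie2, list(rectMask(1:2, 1:2, c(2, 2)))))[1, 1]), 2.5)
})

test_that("render -> extract round trip is exact for disjoint masks", {
  sched <- gridSchedule(c(30, 60))
  truth <- makeGroundTruth(2, "v1_soma", seed = 2, noiseSigma = 0)
  sim <- simulateNeuralTraces(sched, truth, 15, seed = 1)
  masks <- list(rectMask(1:2, 1:2, c(6, 6)), rectMask(4:5, 4:5, c(6, 6)))
  movie <- renderMovie(sim$recording, masks, c(6, 6))
  back <- extractRoiTraces(movie, masks, 15)
  expect_equal(rawTrace(back), rawTrace(sim$recording), tolerance = 1e-12)
})

test_that("overlapping masks mix traces by pixel-overlap fractions", {
  raw <- rbind(c(10, 20), c(100, 50))
  rec <- toyRecording(raw)
  mA <- rectMask(1:2, 1:2, c(4, 4))          # 4 px
  mB <- rectMask(2:3, 2:3, c(4, 4))          # 4 px, 1 px overlap with A
  expect_warning(movie <- renderMovie(rec, list(mA, mB), c(4, 4)),
                 "overlap")
  tr <- rawTrace(extractRoiTraces(movie, list(mA, mB), 15))
  # mask A sees all of its own signal plus 1/4 of B's
  expect_equal(unname(tr[1, ]), raw[1, ] + raw[2, ] / 4)
  expect_equal(unname(tr[2, ]), raw[2, ] + raw[1, ] / 4)
})

test_that("movies survive a TIFF stack round trip", {
  movie <- array(runif(4 * 4 * 3, 0, 50), c(4, 4, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  writeTiffStack(movie, path, scale = 50)
  back <- readTiffStack(path, scale = 50)
  expect_equal(back, movie, tolerance = 1e-6)
})

test_that("trial alignment follows the at-or-after onset-frame convention", {
  nFrames <- 200
  x <- matrix(seq_len(nFrames), 1)  # trace encodes the frame index
  rec <- toyRecording(x)
  d <- methods::new("DffTraceSet", dff = rawTrace(rec), medians = 1,
                    frameRate = 15, provenance = list())
  # onset at exactly frame 100's start time: (100 - 1) / 15
  sched <- gridSchedule((100 - 1) / 15)
  tt <- alignTrials(d, sched, "visual_onset", c(pre = 10, post = 15))
  expect_equal(as.vector(tt@values[1, 1, ]), 90:115)
  # onset strictly between frames -> first frame at/after the onset
  sched2 <- gridSchedule((100 - 1) / 15 + 0.01)
  tt2 <- alignTrials(d, sched2, "visual_onset", c(pre = 0, post = 0))
  expect_equal(as.vector(tt2@values[1, 1, ]), 101)
})

test_that("out-of-bounds trials are dropped and accounted for", {
  d <- methods::new("DffTraceSet", dff = matrix(0, 1, 100), medians = 1,
                    frameRate = 15, provenance = list())
  sched <- gridSchedule(c(0.2, 3, 50))   # first and last overflow the window
  tt <- alignTrials(d, sched, "visual_onset", c(pre = 10, post = 15))
  expect_identical(nTrials(tt) + nrow(tt@dropped), 3L)
  expect_identical(nTrials(tt), 1L)
  expect_match(tt@dropped$reason, "outside")
  expect_error(alignTrials(d, gridSchedule(500), "visual_onset"),
               "no trial")
})

test_that("windowed responses are baseline-subtracted window means", {
  relBins <- -12:16
  v <- array(0, c(1, 1, length(relBins)))
  w <- windowSpec(15)
  v[1, 1, relBins %in% baselineBins(w)] <- 0.1
  v[1, 1, relBins %in% responseBins(w)] <- 0.4
  tt <- toyTensor(v, relBins)
  expect_equal(responses(quantifyResponse(tt, w))$response, 0.3)
  # identical levels -> 0; all-zero block -> 0
  v2 <- array(0.2, c(1, 1, length(relBins)))
  expect_equal(responses(quantifyResponse(toyTensor(v2, relBins), w))$response, 0)
  v3 <- array(0, c(1, 1, length(relBins)))
  expect_equal(responses(quantifyResponse(toyTensor(v3, relBins), w))$response, 0)
})

test_that("full zero-noise round trip matches the closed-form oracle", {
  sched <- gridSchedule(c(30, 60, 90))
  truth <- makeGroundTruth(3, "v1_soma", seed = 1, noiseSigma = 0)
  sim <- simulateNeuralTraces(sched, truth, 15, seed = 1)
  masks <- list(rectMask(1:2, 1:2, c(8, 8)), rectMask(3:4, 3:4, c(8, 8)),
                rectMask(5:6, 5:6, c(8, 8)))
  movie <- renderMovie(sim$recording, masks, c(8, 8))
  rt <- quantifyResponse(
    alignTrials(computeDff(extractRoiTraces(movie, masks, 15)), sched,
                "visual_onset"),
    windowSpec(15))
  est <- roiMeans(rt, "Va")
  oracle <- truth@roi$vis_amp_a * windowGain(windowSpec(15))
  expect_lt(max(abs(unname(est) - oracle)), 1e-9)
})
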