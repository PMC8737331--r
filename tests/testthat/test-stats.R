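test_that("normality gate selects parametric vs non-parametric branches", {
  set.seed(11)
  # Gaussian samples: parametric branch in >= 95% of replicates
  paraG <- vapply(1:100, function(i)
    grepl("t-test", dispatchTest(rnorm(200), design = "one_sample")$test),
    logical(1))
  expect_gte(mean(paraG), 0.95)
  # heavy-tailed samples: non-parametric branch in the majority
  paraL <- vapply(1:100, function(i)
    grepl("t-test", dispatchTest(rlnorm(200), mu = exp(0.5),
                                 design = "one_sample")$test),
    logical(1))
  expect_lt(mean(paraL), 0.5)
})

test_that("dispatcher handles degenerate and small samples", {
  x <- c(1, 2, 3, 4, 5)
  res <- dispatchTest(x, x, design = "paired")
  expect_equal(res$p.value, 1)
  expect_match(res$test, "degenerate")
  # below n = 4 the normality test is skipped: non-parametric by default
  small <- dispatchTest(c(1, 2, 3), c(2, 3, 5), design = "paired")
  expect_match(small$test, "Wilcoxon")
  expect_match(small$note, "normality not assessed")
  expect_error(dispatchTest(1, design = "one_sample"))
  expect_error(dispatchTest(1:3, 1:4, design = "paired"), "equal length")
})

test_that("response difference index follows its definition", {
  res <- responseDifferenceIndex(cued = c(r1 = 1), uncued = c(r1 = 2),
                                 normReference = 2)
  expect_equal(unname(res@perRoi), 0.5)
  # cued == uncued per ROI -> all indices 0, no effect declared
  x <- rnorm(20)
  res0 <- responseDifferenceIndex(x, x, normReference = 1.5)
  expect_true(all(res0@perRoi == 0))
  expect_equal(res0@test$p.value, 1)
  expect_error(responseDifferenceIndex(1:3, 1:3, 0), "zero")
  expect_error(responseDifferenceIndex(1:3, 1:4, 1), "same ROIs")
})

test_that("consecutive-bin rule flags only runs of the minimum length", {
  p <- c(0.04, 0.03, 0.01, 0.20, 0.04, 0.04)
  rf <- crossmodal:::.runFlags(p < 0.05, 3L)
  expect_identical(rf$flags, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(nrow(rf$runs), 1L)
  expect_identical(c(rf$runs$start, rf$runs$end), c(1L, 3L))
})

test_that("binwise test is silent for identical tensors and detects true differences", {
  relBins <- -12:16
  set.seed(3)
  v <- array(rnorm(30 * 8 * length(relBins), 0, 0.05),
             c(30, 8, length(relBins)))
  tt <- toyTensor(v, relBins)
  w <- windowSpec(15)
  expect_identical(sum(binwiseDifferenceTest(tt, tt, window = w)@significant), 0L)
  # add a response in bins 4..14 of set B
  v2 <- v
  v2[, , relBins %in% 4:14] <- v2[, , relBins %in% 4:14] + 0.5
  res <- binwiseDifferenceTest(toyTensor(v2, relBins), tt, window = w)
  expect_true(all(res@significant))
  expect_error(binwiseDifferenceTest(tt, toyTensor(v[1:10, , ], relBins),
                                     window = w), "identical ROI sets")
})

test_that("binwise flags are monotone in alpha", {
  relBins <- -12:16
  set.seed(8)
  v1 <- array(rnorm(40 * 10 * length(relBins), 0, 0.1),
              c(40, 10, length(relBins)))
  v2 <- v1 + array(rnorm(length(v1), 0.02, 0.1), dim(v1))
  w <- windowSpec(15)
  f1 <- binwiseDifferenceTest(toyTensor(v1, relBins), toyTensor(v2, relBins),
                              window = w, alpha = 0.01)@significant
  f2 <- binwiseDifferenceTest(toyTensor(v1, relBins), toyTensor(v2, relBins),
                              window = w, alpha = 0.1)@significant
  expect_true(all(f2[f1]))   # flags at the stricter alpha survive relaxation
})

test_that("responsiveness classification compares response to baseline across trials", {
  relBins <- -12:16
  w <- windowSpec(15)
  set.seed(5)
  n <- length(relBins)
  v <- array(rnorm(2 * 20 * n, 0, 0.02), c(2, 20, n))
  # ROI 1 responds; ROI 2 is response == baseline by construction
  v[1, , relBins %in% responseBins(w)] <-
    v[1, , relBins %in% responseBins(w)] + 0.5
  v[2, , ] <- 0.1
  cls <- classifyResponsive(toyTensor(v, relBins), w)
  expect_true(cls$responsive[["roi0001"]])
  expect_false(isTRUE(cls$responsive[["roi0002"]]))
  # simulated population: ~40% responsive at high SNR
  truth <- makeGroundTruth(80, "auc_axon", seed = 2, noiseSigma = 0.05,
                           responsiveFraction = 0.4)
  sched <- makeTrialSchedule(scheduleConfig(days = 1, trialsPerDay = 40), 3)
  sim <- simulateNeuralTraces(sched, truth, 15, seed = 4)
  tt <- alignTrials(computeDff(sim$recording), sched, "visual_onset")
  frac <- classifyResponsive(tt, w)$fraction
  truthFrac <- mean(truth@roi$vis_amp_a > 0 | truth@roi$vis_amp_b > 0 |
                      truth@roi$vis_amp_c > 0 | truth@roi$aud_amp_a > 0 |
                      truth@roi$aud_amp_b > 0)
  expect_lt(abs(frac - truthFrac), 3.5 * sqrt(0.4 * 0.6 / 80) + 0.05)
})

test_that("normalized suppression follows its formula and sign convention", {
  w1 <- matrix(1, 4, 10); w0 <- matrix(0.25, 4, 10)
  res <- normalizedSuppression(respWith = w0, respWithout = w1)
  expect_equal(unname(res$suppression), rep(0.75, 4))
  same <- normalizedSuppression(w1, w1)
  expect_true(all(same$suppression == 0))
  expect_error(normalizedSuppression(w1, matrix(0, 4, 10)), "zero response")
  # per-ROI denominator option
  perRoi <- normalizedSuppression(w0, w1, denominator = "roi")
  expect_equal(unname(perRoi$suppression), rep(0.75, 4))
})

test_that("opto-influence classification is a total sign partition", {
  x <- c(a = 0.1, b = -0.1, c = 2, d = -3)
  cls <- classifyFmi(x)
  expect_identical(as.character(cls[c("a", "c")]), c("excited", "excited"))
  expect_identical(as.character(cls[c("b", "d")]), c("inhibited", "inhibited"))
  expect_identical(length(cls), length(x))
  # exact zeros go to inhibited, with a warning, keeping the partition total
  expect_warning(cls0 <- classifyFmi(c(0, 0, 1)), "zero")
  expect_identical(as.character(cls0), c("inhibited", "inhibited", "excited"))
  expect_identical(sum(table(cls0)), 3L)
  expect_error(classifyFmi(c(1, NA)), "finite")
  # property: partition is total for arbitrary finite inputs
  set.seed(2)
  for (i in 1:20) {
    z <- rnorm(50)
    expect_identical(sum(table(classifyFmi(z))), 50L)
  }
})

test_that("population correlation reports r, r squared, and undefined cases", {
  a <- rnorm(30)
  expect_equal(populationCorrelation(a, 2 * a)$r, 1)
  expect_equal(populationCorrelation(a, -a)$r, -1)
  res <- populationCorrelation(a, 3 + a * 0.5)
  expect_equal(res$r2, res$r^2)
  flat <- populationCorrelation(a, rep(1, 30))
  expect_true(is.na(flat$r))
  expect_match(flat$reason, "undefined")
  expect_error(populationCorrelation(1:2, 1:2), "at least 3")
})

test_that("unreinforced conditions pool by per-ROI averaging", {
  x <- list(Va = c(0.2, 0.4), Vb = c(0.4, 0.2), AaVa = c(1, 2),
            AbVb = c(3, 4), Aa = c(0.1, 0.1), Ab = c(0.3, 0.5))
  pooled <- poolUnreinforced(x)
  expect_equal(pooled$Vo, c(0.3, 0.3))
  expect_equal(pooled$AoVo, c(2, 3))
  expect_equal(pooled$Ao, c(0.2, 0.3))
  # identical constituents pool to themselves
  expect_equal(poolUnreinforced(list(Va = c(1, 2), Vb = c(1, 2)))$Vo, c(1, 2))
  expect_error(poolUnreinforced(list(Va = 1:3)), "requires both")
})

test_that("group comparison detects group-specific visual differences", {
  relBins <- -12:16
  w <- windowSpec(15)
  set.seed(7)
  n <- length(relBins)
  v <- array(rnorm(40 * 10 * n, 0, 0.05), c(40, 10, n))
  labels <- factor(rep(c("inhibited", "excited"), each = 20),
                   levels = c("inhibited", "excited"))
  # inhibited group responds more strongly in the response window
  v[1:20, , relBins %in% responseBins(w)] <-
    v[1:20, , relBins %in% responseBins(w)] + 0.4
  res <- compareGroupResponses(labels, toyTensor(v, relBins), w)
  expect_gt(nrow(res$binwise@runs), 0L)
  expect_identical(unname(res$n), c(20L, 20L))
  # identical groups: no flags
  v0 <- array(rnorm(40 * 10 * n, 0, 0.05), c(40, 10, n))
  res0 <- compareGroupResponses(labels, toyTensor(v0, relBins), w)
  expect_identical(sum(res0$binwise@significant), 0L)
  # single-ROI group exercises the error contract
  lab1 <- factor(c("inhibited", rep("excited", 39)),
                 levels = c("inhibited", "excited"))
  expect_error(compareGroupResponses(lab1, toyTensor(v, relBins), w),
               "at least 2")
})
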