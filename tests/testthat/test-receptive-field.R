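test_that("visual-space maps bin responses with missing (not zero) empty cells", {
  grid <- rfGrid(nx = 4, ny = 3)
  # single response at one position: exactly one non-missing cell
  map <- mapVisualSpace(resp = 0.8, positions = cbind(0.9, 0.1), grid)
  expect_identical(sum(!is.na(map@mean)), 1L)
  expect_equal(max(map@mean, na.rm = TRUE), 0.8)
  expect_true(all(map@n[is.na(map@mean)] == 0))
  # uniform responses at every cell centre: flat map, peak norm = that value
  centres <- expand.grid(x = crossmodal:::.gridCenters(c(0, 1), 4),
                         y = crossmodal:::.gridCenters(c(0, 1), 3))
  flat <- mapVisualSpace(rep(0.5, nrow(centres)), centres, grid)
  expect_true(all(flat@mean == 0.5))
  nflat <- normalizeRf(flat)
  expect_equal(nflat@normConstant, 0.5)
  expect_true(all(nflat@mean == 1))
  expect_error(mapVisualSpace(1, cbind(2, 0.5), grid), "outside")
})

test_that("peak normalization is idempotent", {
  set.seed(1)
  centres <- expand.grid(x = crossmodal:::.gridCenters(c(0, 1), 4),
                         y = crossmodal:::.gridCenters(c(0, 1), 3))
  map <- mapVisualSpace(runif(nrow(centres)), centres, rfGrid(nx = 4, ny = 3))
  once <- normalizeRf(map)
  twice <- normalizeRf(once)
  expect_equal(twice@mean, once@mean)
  expect_equal(twice@normConstant, once@normConstant)
  expect_equal(max(once@mean, na.rm = TRUE), 1)
})

test_that("peak location takes the argmax with lowest-coordinate tie-break", {
  grid <- rfGrid(nx = 4, ny = 3)
  centres <- expand.grid(x = crossmodal:::.gridCenters(c(0, 1), 4),
                         y = crossmodal:::.gridCenters(c(0, 1), 3))
  r <- rep(0.1, nrow(centres))
  r[centres$x > 0.5 & centres$x < 0.75 & centres$y > 1 / 3 & centres$y < 2 / 3] <- 1
  pk <- peakLocation(mapVisualSpace(r, centres, grid))
  expect_identical(c(pk$ix, pk$iy), c(3L, 2L))
  # flat map: first cell by tie-break, with a warning
  flat <- mapVisualSpace(rep(1, nrow(centres)), centres, grid)
  expect_warning(pk0 <- peakLocation(flat), "tie")
  expect_identical(c(pk0$ix, pk0$iy), c(1L, 1L))
})

test_that("simulated Gaussian receptive fields are recovered within one grid step", {
  grid <- rfGrid(nx = 8, ny = 6)
  sched <- makeRfSchedule(grid, nRepeats = 2, seed = 2)
  truth <- makeGroundTruth(25, "auc_axon", seed = 3, noiseSigma = 0.05)
  truth@roi$rf_sigma[] <- 0.15
  sim <- simulateNeuralTraces(sched, truth, 15, seed = 4)
  rt <- quantifyResponse(
    alignTrials(computeDff(sim$recording), sched, "visual_onset"),
    windowSpec(15))
  tab <- responses(rt)
  stepX <- 1 / grid$nx; stepY <- 1 / grid$ny
  hits <- vapply(unique(tab$roi_id), function(id) {
    sub <- tab[tab$roi_id == id, ]
    map <- mapVisualSpace(sub$response, sub[, c("pos_x", "pos_y")], grid)
    pk <- peakLocation(map)
    i <- match(id, truth@roi$roi_id)
    abs(pk$x - truth@roi$rf_x[i]) <= 1.5 * stepX &&
      abs(pk$y - truth@roi$rf_y[i]) <= 1.5 * stepY
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
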