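#' @include AllClasses.R
NULL

#' Run configuration for end-to-end synthetic experiments
#'
#' @param seed Master seed; expanded into named child streams
#'   (schedule/neural/behavior/opto) via [childSeed()].
#' @param scenario Ground-truth scenario (see [makeGroundTruth()]).
#' @param nRoi,population,days,trialsPerDay,frameRate,behaviorRate
#'   Generator sizes and rates.
#' @param alpha,minConsecutive Analysis test parameters.
#' @return Validated config list.
#' @export
runConfig <- function(seed = 1, scenario = "default", nRoi = 100,
                      population = "v1_soma", days = 1:5, trialsPerDay = 120,
                      frameRate = 15, behaviorRate = 100, alpha = 0.05,
                      minConsecutive = 3) {
  cfg <- list(seed = as.integer(seed), scenario = scenario,
              nRoi = as.integer(nRoi), population = population,
              days = as.integer(days), trialsPerDay = as.integer(trialsPerDay),
              frameRate = frameRate, behaviorRate = behaviorRate,
              alpha = alpha, minConsecutive = as.integer(minConsecutive))
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  need <- c("seed", "scenario", "nRoi", "population", "days", "trialsPerDay",
            "frameRate", "behaviorRate", "alpha", "minConsecutive")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    .configError("config fields missing: ", paste(missing, collapse = ", "))
  if (cfg$nRoi < 1 || cfg$trialsPerDay < 1 || cfg$frameRate <= 0 ||
      cfg$behaviorRate <= 0 || cfg$alpha <= 0 || cfg$alpha >= 1)
    .configError("config values out of range")
  invisible(TRUE)
}

#' Read a run configuration from JSON or YAML
#'
#' Fields missing from the file fall back to [runConfig()] defaults; the
#' merged configuration is schema-validated before any work happens.
#'
#' @param path `.json` or `.yaml`/`.yml` file.
#' @return Validated config list.
#' @export
readRunConfig <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .configError("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(runConfig(), x)
  .validateConfig(cfg)
  cfg
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes a dataset directory containing the trial schedule (CSV), the raw
#' fluorescence recording and behaviour (RDS), the ground-truth sidecar
#' (JSON) and a copy of the config (JSON). Deterministic in
#' `(config, seed)`.
#'
#' @param config From [runConfig()].
#' @param outDir Output directory (created).
#' @return Invisibly, the list of generated objects.
#' @export
runSimulate <- function(config, outDir) {
  .validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  truth <- makeGroundTruth(config$nRoi, config$population, config$scenario,
                           seed = childSeed(config$seed, "truth"))
  schedule <- makeTrialSchedule(
    scheduleConfig(days = config$days, trialsPerDay = config$trialsPerDay),
    seed = childSeed(config$seed, "schedule"))
  neural <- simulateNeuralTraces(schedule, truth, config$frameRate,
                                 seed = childSeed(config$seed, "neural"))
  behavior <- simulateBehavior(schedule, truth, config$behaviorRate,
                               seed = childSeed(config$seed, "behavior"))
  jsonlite::write_json(config, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeTrialSchedule(schedule, file.path(outDir, "schedule.csv"))
  writeGroundTruth(truth, file.path(outDir, "truth.json"))
  saveRDS(neural$recording, file.path(outDir, "recording.rds"))
  saveRDS(behavior, file.path(outDir, "behavior.rds"))
  invisible(list(truth = truth, schedule = schedule,
                 recording = neural$recording, behavior = behavior))
}

#' Response difference index per conditioning day
#'
#' Convenience over [responseDifferenceIndex()]: the normalization constant
#' is the day-1 population mean un-cued response, computed once and reused
#' for every day.
#'
#' @param responseTable A [ResponseTable-class].
#' @param cued,uncued Condition labels compared.
#' @param refDay Day whose un-cued mean defines the normalization
#'   (default: the earliest day present).
#' @return data.frame: day, index mean, sem, p, n.
#' @export
indexByDay <- function(responseTable, cued = "AaVa", uncued = "Va",
                       refDay = NULL) {
  tab <- responses(responseTable)
  days <- sort(unique(tab$day[tab$condition %in% c(cued, uncued)]))
  if (is.null(refDay)) refDay <- min(tab$day[tab$condition %in% uncued])
  norm <- mean(roiMeans(responseTable, uncued, refDay), na.rm = TRUE)
  out <- lapply(days, function(d) {
    cu <- roiMeans(responseTable, cued, d)
    un <- roiMeans(responseTable, uncued, d)
    ok <- !is.na(cu) & !is.na(un)
    res <- responseDifferenceIndex(cu[ok], un[ok], norm)
    data.frame(day = d, index = res@mean, sem = res@sem,
               p = res@test$p.value, test = res@test$test, n = sum(ok))
  })
  do.call(rbind, out)
}

#' Analyze a synthetic (or real) dataset end to end
#'
#' Runs dF/F conversion, trial alignment, windowed response
#' quantification, the day-wise response difference index, the day-4 (or
#' last-day) bin-by-bin cued vs un-cued comparison, anticipatory-lick
#' fractions with day-wise cued vs un-cued dispatch tests, and running
#' aggregates. Results are written as tidy CSV/JSON when `outDir` is
#' given.
#'
#' @param dataset Either a dataset directory from [runSimulate()] or a
#'   list with `recording`, `schedule`, `behavior`.
#' @param config From [runConfig()] (read from the dataset directory when
#'   present).
#' @param outDir Optional output directory.
#' @return Analysis report list.
#' @export
runAnalyze <- function(dataset, config = NULL, outDir = NULL) {
  if (is.character(dataset)) {
    dir <- dataset
    if (is.null(config))
      config <- jsonlite::read_json(file.path(dir, "config.json"),
                                    simplifyVector = TRUE)
    dataset <- list(
      recording = readRDS(file.path(dir, "recording.rds")),
      schedule = readTrialSchedule(file.path(dir, "schedule.csv")),
      behavior = readRDS(file.path(dir, "behavior.rds")))
  }
  if (is.null(config)) config <- runConfig()
  .validateConfig(config)

  dffSet <- computeDff(dataset$recording)
  window <- windowSpec(frameRate(dffSet))
  tensor <- alignTrials(dffSet, dataset$schedule, "visual_onset")
  rt <- quantifyResponse(tensor, window)
  idx <- indexByDay(rt)

  lastDay <- max(trialInfo(tensor)$day)
  sub <- function(cond, day) {
    sel <- trialInfo(tensor)$condition == cond & trialInfo(tensor)$day == day
    if (!any(sel)) return(NULL)
    methods::new("TrialTensor", values = tensor@values[, sel, , drop = FALSE],
                 relBins = relBins(tensor),
                 trials = trialInfo(tensor)[sel, , drop = FALSE],
                 alignTo = tensor@alignTo, frameRate = frameRate(tensor),
                 dropped = tensor@dropped)
  }
  tA <- sub("AaVa", lastDay); tV <- sub("Va", lastDay)
  binwise <- if (!is.null(tA) && !is.null(tV))
    binwiseDifferenceTest(tA, tV, window = window, alpha = config$alpha,
                          minConsecutive = config$minConsecutive) else NULL

  behavior <- dataset$behavior
  events <- detectLicks(behavior@lickVoltage, behavior@lickRate)
  lick <- anticipatoryLicking(events, dataset$schedule)
  lickTests <- lapply(sort(unique(lick$trials$day)), function(d) {
    a <- lick$trials$any_lick[lick$trials$condition == "AaVa" &
                                lick$trials$day == d]
    v <- lick$trials$any_lick[lick$trials$condition == "Va" &
                                lick$trials$day == d]
    if (length(a) < 2 || length(v) < 2) return(NULL)
    ht <- dispatchTest(as.numeric(a), as.numeric(v), design = "unpaired")
    data.frame(day = d, p = ht$p.value, test = ht$test,
               frac_cued = mean(a), frac_uncued = mean(v))
  })
  lickTests <- do.call(rbind, lickTests)
  running <- quantifyRunning(behavior@speed, behavior@speedRate,
                             dataset$schedule)

  report <- list(config = config, index = idx, binwise = binwise,
                 lickFractions = lick$fractions, lickTests = lickTests,
                 running = running$aggregates,
                 provenance = list(
                   filter = dffSet@provenance$filter,
                   droppedTrials = nrow(tensor@dropped),
                   aggregationUnit = rt@aggregationUnit))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(idx, file.path(outDir, "index_by_day.csv"),
                     row.names = FALSE)
    utils::write.csv(responses(rt), file.path(outDir, "responses.csv"),
                     row.names = FALSE)
    utils::write.csv(lick$fractions, file.path(outDir, "lick_fractions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      index = idx, lickTests = lickTests,
      binwiseFlaggedBins = if (is.null(binwise)) integer(0) else
        binwise@bins[binwise@significant],
      provenance = report$provenance),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Parameter-recovery study for the response difference index
#'
#' For each generative suppression factor, simulates replicate single-day
#' sessions (cued + un-cued trials), runs the full trace pipeline and
#' estimates the population response difference index; reports bias, RMSE
#' and Monte-Carlo s.e. against the ground truth.
#'
#' @param suppressionGrid Generative suppression factors.
#' @param nReplicates Replicates per grid value (>= 2).
#' @param nRoi ROIs per replicate.
#' @param trialsPerCondition Trials per condition per replicate.
#' @param seed Master seed.
#' @param noiseSigma Generative dF/F noise s.d.
#' @return data.frame: truth, mean estimate, bias, rmse, mc_se, n.
#' @export
runRecover <- function(suppressionGrid = c(0, 0.15, 0.3), nReplicates = 20,
                       nRoi = 500, trialsPerCondition = 40, seed = 1,
                       noiseSigma = 0.1) {
  if (nReplicates < 2) .configError("nReplicates must be >= 2")
  est <- matrix(NA_real_, length(suppressionGrid), nReplicates)
  for (si in seq_along(suppressionGrid)) {
    s <- suppressionGrid[si]
    for (r in seq_len(nReplicates)) {
      sd0 <- childSeed(seed, sprintf("recover_%d_%d", si, r))
      est[si, r] <- .estimateIndexOnce(s, nRoi, trialsPerCondition, sd0,
                                       noiseSigma)
    }
  }
  data.frame(truth = suppressionGrid,
             estimate = rowMeans(est),
             bias = rowMeans(est) - suppressionGrid,
             rmse = sqrt(rowMeans((est - suppressionGrid)^2)),
             mc_se = apply(est, 1L, sem),
             n = nReplicates)
}

# one replicate: simulate a single-day cued/un-cued session and estimate
# the index through the full pipeline
.estimateIndexOnce <- function(suppression, nRoi, trialsPerCondition, seed,
                               noiseSigma = 0.1) {
  truth <- makeGroundTruth(nRoi, "v1_soma", "default",
                           seed = childSeed(seed, "truth"),
                           suppression = rep(suppression, 5),
                           noiseSigma = noiseSigma)
  cfg <- scheduleConfig(days = 1, trialsPerDay = 2 * trialsPerCondition)
  cfg$uncuedFraction[] <- 0.5
  cfg$vcFractionOfUncued <- 0
  cfg$cuedStimuli <- "AaVa"          # only the rewarded pair and its probe
  cfg$uncuedStimuli <- "Va"
  schedule <- makeTrialSchedule(cfg, seed = childSeed(seed, "schedule"))
  sim <- simulateNeuralTraces(schedule, truth, 15,
                              seed = childSeed(seed, "neural"))
  dffSet <- computeDff(sim$recording)
  tensor <- alignTrials(dffSet, schedule, "visual_onset")
  rt <- quantifyResponse(tensor, windowSpec(15))
  idx <- indexByDay(rt)
  idx$index[1L]
}
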