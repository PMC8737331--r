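#' @include AllClasses.R align.R
NULL

#' Normality-gated statistical test dispatch
#'
#' Samples are first tested for normality with a Lilliefors
#' (Kolmogorov--Smirnov) test at alpha 0.05 (on the paired differences for
#' paired/one-sample designs, on each sample for unpaired designs). When
#' normality is not rejected, the parametric branch is used (paired,
#' one-sample or two-sample t-test); otherwise the non-parametric analogue
#' (Wilcoxon signed-rank or rank-sum). All tests are two-sided. Samples
#' smaller than 4 skip the normality test and default to the
#' non-parametric branch. Degenerate zero-variance differences return
#' p = 1 (no effect).
#'
#' @param x Numeric sample.
#' @param y Second sample (required for paired/unpaired designs).
#' @param design `"paired"`, `"unpaired"` or `"one_sample"` (vs `mu`).
#' @param mu Null value for the one-sample design.
#' @param normalityAlpha Alpha of the Lilliefors gate.
#' @return List: `test`, `p.value`, `statistic`, `n`, `design`,
#'   `normal` (gate outcome), `note`.
#' @examples
#' dispatchTest(rnorm(50), design = "one_sample")
#' @export
dispatchTest <- function(x, y = NULL,
                         design = c("paired", "unpaired", "one_sample"),
                         mu = 0, normalityAlpha = 0.05) {
  design <- match.arg(design)
  x <- as.numeric(x)
  if (design != "one_sample") {
    if (is.null(y)) .configError("design '", design, "' requires two samples")
    y <- as.numeric(y)
  }
  if (design == "paired" && length(x) != length(y))
    .dataError("paired design requires samples of equal length")
  nEff <- if (design == "unpaired") min(length(x), length(y)) else length(x)
  if (nEff < 2L) .dataError("need at least 2 observations per sample")

  isNormal <- function(v) {
    if (length(v) < 4L) return(NA)       # too small: non-parametric default
    if (stats::sd(v) == 0) return(NA)
    nortest::lillie.test(v)$p.value >= normalityAlpha
  }

  note <- NULL
  if (design %in% c("paired", "one_sample")) {
    d <- if (design == "paired") x - y else x - mu
    if (stats::sd(d) == 0) {
      return(list(test = "degenerate (zero-variance differences)",
                  p.value = 1, statistic = NA_real_, n = length(d),
                  design = design, normal = NA,
                  note = "no variability; no effect declared"))
    }
    normal <- isNormal(d)
    if (isTRUE(normal)) {
      ht <- stats::t.test(d, mu = 0)
      test <- if (design == "paired") "paired t-test" else "one-sample t-test"
    } else {
      if (is.na(normal)) note <- "normality not assessed (n < 4 or degenerate)"
      ht <- stats::wilcox.test(d, mu = 0, exact = FALSE, correct = TRUE)
      test <- "Wilcoxon signed-rank test"
    }
  } else {
    nx <- isNormal(x); ny <- isNormal(y)
    normal <- isTRUE(nx) && isTRUE(ny)
    if (normal) {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      test <- "unpaired t-test"
    } else {
      if (is.na(nx) || is.na(ny))
        note <- "normality not assessed (n < 4 or degenerate)"
      ht <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
      test <- "Wilcoxon rank-sum test"
    }
  }
  list(test = test, p.value = as.numeric(ht$p.value),
       statistic = as.numeric(ht$statistic), n = nEff, design = design,
       normal = normal, note = note)
}

#' Response difference index between cued and un-cued visual responses
#'
#' Per-ROI index `(uncued - cued) / normReference`, where the normalization
#' constant is the population mean un-cued response on day 1 of
#' conditioning (computed once and reused for all days). The subtractive
#' form avoids per-trial division-by-zero problems; a zero day-1 reference
#' is still fatal and reported as an error. Positive values denote
#' cue-driven suppression. The population is compared against 0 with the
#' normality-gated dispatcher (two-sided).
#'
#' @param cued,uncued Per-ROI mean responses (same ROIs, same order), e.g.
#'   from [roiMeans()].
#' @param normReference Scalar day-1 mean un-cued response.
#' @return A [ResponseDifferenceResult-class].
#' @examples
#' responseDifferenceIndex(cued = c(1, 1), uncued = c(2, 2), normReference = 2)
#' @export
responseDifferenceIndex <- function(cued, uncued, normReference) {
  if (length(cued) != length(uncued))
    .dataError("cued and un-cued slices must cover the same ROIs")
  if (length(normReference) != 1L || !is.finite(normReference) ||
      normReference == 0)
    .dataError("normalization reference (day-1 mean un-cued response) is zero or non-finite")
  idx <- (as.numeric(uncued) - as.numeric(cued)) / normReference
  names(idx) <- names(cued)
  test <- if (length(idx) >= 2L) dispatchTest(idx, design = "one_sample")
          else list(test = "not run (single ROI)", p.value = NA_real_,
                    n = length(idx))
  methods::new("ResponseDifferenceResult", perRoi = idx, mean = mean(idx),
               sem = sem(idx), normReference = as.numeric(normReference),
               test = test)
}

# two-sided t-test p-value with a degenerate-variance guard: identical
# samples give NA (no evidence either way), an exactly constant non-zero
# difference gives 0 (infinite t)
.safeTTestP <- function(x, y = NULL) {
  if (is.null(y)) {
    if (stats::sd(x) <= 1e-12 * max(abs(mean(x)), 1e-12))
      return(if (abs(mean(x)) <= 1e-12) NA_real_ else 0)
    stats::t.test(x)$p.value
  } else {
    if (stats::sd(x) <= 1e-12 && stats::sd(y) <= 1e-12)
      return(if (abs(mean(x) - mean(y)) <= 1e-12) NA_real_ else 0)
    stats::t.test(x, y, var.equal = TRUE)$p.value
  }
}

# per-ROI, per-bin trial-averaged baseline-subtracted values
.binValues <- function(tensor, bins, baselineBins) {
  bi <- .binIndex(tensor, baselineBins)
  base <- .sliceMean(tensor@values, bi)
  out <- vapply(bins, function(b) {
    v <- .sliceMean(tensor@values, .binIndex(tensor, b))
    rowMeans(v - base)
  }, numeric(dim(tensor@values)[1L]))
  matrix(out, nrow = dim(tensor@values)[1L],
         dimnames = list(roiIds(tensor), as.character(bins)))
}

.runFlags <- function(sig, minConsecutive) {
  flags <- rep(FALSE, length(sig))
  runs <- data.frame(start = integer(0), end = integer(0))
  r <- rle(ifelse(is.na(sig), FALSE, sig))
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] >= minConsecutive) {
      i0 <- pos[k]; i1 <- pos[k] + r$lengths[k] - 1L
      flags[i0:i1] <- TRUE
      runs <- rbind(runs, data.frame(start = i0, end = i1))
    }
  }
  list(flags = flags, runs = runs)
}

#' Bin-by-bin response difference test with a consecutive-bin rule
#'
#' Compares two aligned response sets bin by bin, in one-frame (66.7 ms at
#' 15 Hz) time bins: per ROI and bin the trial-averaged,
#' baseline-subtracted dF/F is computed for each set, then each bin is
#' tested across ROIs with a two-sided t-test (paired when both sets cover
#' the same ROIs, unpaired for disjoint groups). Bins are flagged
#' significant only within maximal runs of at least `minConsecutive`
#' consecutive bins with `p < alpha`; no further multiple-testing
#' correction is applied.
#'
#' @param tensorA,tensorB [TrialTensor-class] objects (identical ROI sets
#'   when `paired = TRUE`), or numeric ROI x bin matrices of precomputed
#'   bin values.
#' @param bins Relative bins to test (default: the response window).
#' @param window A [WindowSpec-class] supplying default bins and baseline.
#' @param alpha Per-bin significance level.
#' @param minConsecutive Minimum run length for flagging.
#' @param paired Pairing unit is the ROI; set `FALSE` for disjoint groups.
#' @return A [BinwiseTestResult-class].
#' @export
binwiseDifferenceTest <- function(tensorA, tensorB,
                                  window = NULL, bins = NULL,
                                  alpha = 0.05, minConsecutive = 3,
                                  paired = TRUE) {
  if (methods::is(tensorA, "TrialTensor")) {
    if (is.null(window)) window <- windowSpec(frameRate(tensorA))
    if (is.null(bins)) bins <- responseBins(window)
    A <- .binValues(tensorA, bins, baselineBins(window))
    B <- .binValues(tensorB, bins, baselineBins(window))
  } else {
    A <- as.matrix(tensorA); B <- as.matrix(tensorB)
    if (is.null(bins)) bins <- seq_len(ncol(A))
  }
  if (ncol(A) != ncol(B)) .dataError("bin axes differ between the two sets")
  if (paired) {
    if (nrow(A) != nrow(B) ||
        (!is.null(rownames(A)) && !is.null(rownames(B)) &&
         !identical(rownames(A), rownames(B))))
      .dataError("paired binwise test requires identical ROI sets")
    if (nrow(A) < 2L) .dataError("need at least 2 ROIs")
  } else if (nrow(A) < 2L || nrow(B) < 2L) {
    .dataError("need at least 2 ROIs per group")
  }
  p <- vapply(seq_len(ncol(A)), function(b) {
    if (paired) .safeTTestP(A[, b] - B[, b])
    else .safeTTestP(A[, b], B[, b])
  }, numeric(1))
  sig <- !is.na(p) & p < alpha
  rf <- .runFlags(sig, minConsecutive)
  runs <- rf$runs
  if (nrow(runs)) {
    runs$start_bin <- bins[runs$start]; runs$end_bin <- bins[runs$end]
  }
  methods::new("BinwiseTestResult", bins = as.integer(bins), pValues = p,
               significant = rf$flags, runs = runs, alpha = alpha,
               minConsecutive = as.integer(minConsecutive),
               test = if (paired) "paired t-test" else "unpaired t-test")
}

#' Classify ROIs as responsive and summarize responsive fractions
#'
#' Per ROI, the dF/F during the response window is compared to the dF/F
#' during the baseline window across trials (paired, dispatcher-selected
#' test, two-sided). ROIs with fewer than `minTrials` trials are marked
#' indeterminate and excluded from fractions.
#'
#' @param tensor A [TrialTensor-class].
#' @param window A [WindowSpec-class].
#' @param alpha Significance level.
#' @param minTrials Minimum trials per ROI.
#' @return List: `responsive` (named logical, `NA` = indeterminate),
#'   `pValues`, `fraction` (overall), `perMouse` (fraction per mouse when
#'   ROI-mouse assignment is carried by `roiMouse`).
#' @param roiMouse Optional character vector assigning each ROI to a mouse.
#' @export
classifyResponsive <- function(tensor, window = windowSpec(frameRate(tensor)),
                               alpha = 0.05, minTrials = 2, roiMouse = NULL) {
  ri <- .binIndex(tensor, responseBins(window))
  bi <- .binIndex(tensor, baselineBins(window))
  v <- tensor@values
  respTrial <- .sliceMean(v, ri)
  baseTrial <- .sliceMean(v, bi)
  n <- nrow(respTrial)
  pv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ok <- !is.na(respTrial[i, ]) & !is.na(baseTrial[i, ])
    if (sum(ok) < max(2L, minTrials)) next
    pv[i] <- dispatchTest(respTrial[i, ok], baseTrial[i, ok],
                          design = "paired")$p.value
  }
  responsive <- ifelse(is.na(pv), NA, pv < alpha)
  names(responsive) <- names(pv) <- roiIds(tensor)
  out <- list(responsive = responsive, pValues = pv,
              fraction = mean(responsive, na.rm = TRUE))
  if (!is.null(roiMouse)) {
    out$perMouse <- tapply(responsive, roiMouse,
                           function(z) mean(z, na.rm = TRUE))
  }
  out
}

#' Normalized optogenetic suppression
#'
#' Per-ROI fractional reduction of a stimulus response under optogenetic
#' silencing: `(mean_without - mean_with) / |denominator|`, where the
#' denominator is the population mean response without silencing (default)
#' or the per-ROI mean (`denominator = "roi"`). Positive values denote
#' suppression. The population is compared against 0 with the dispatcher.
#'
#' @param respWith,respWithout ROI x trial matrices (or per-ROI lists of
#'   per-trial responses) with and without optogenetic silencing.
#' @param denominator `"population"` or `"roi"`.
#' @return List: `suppression` (per ROI), `mean`, `sem`, `test`,
#'   `denominator`.
#' @export
normalizedSuppression <- function(respWith, respWithout,
                                  denominator = c("population", "roi")) {
  denominator <- match.arg(denominator)
  mWith <- if (is.list(respWith)) vapply(respWith, mean, numeric(1))
           else rowMeans(respWith, na.rm = TRUE)
  mWithout <- if (is.list(respWithout)) vapply(respWithout, mean, numeric(1))
              else rowMeans(respWithout, na.rm = TRUE)
  if (length(mWith) != length(mWithout))
    .dataError("both trial sets must cover the same ROIs")
  popWithout <- mean(mWithout)
  denom <- if (denominator == "population") rep(abs(popWithout), length(mWith))
           else abs(mWithout)
  if (any(denom == 0))
    .dataError("zero response without silencing; suppression undefined")
  s <- (mWithout - mWith) / denom
  list(suppression = s, mean = mean(s), sem = sem(s),
       test = dispatchTest(s, design = "one_sample"),
       denominator = denominator)
}

#' Classify ROIs by their response to optogenetic axon stimulation
#'
#' Sign split of the baseline-subtracted windowed response to axon
#' stimulation: responses greater than 0 are `excited`, responses less
#' than 0 are `inhibited`. Exact zeros are assigned to `inhibited` (fixed
#' tie-break, flagged with a warning), so the labels always partition all
#' ROIs.
#'
#' @param optoResponses Named per-ROI scalar responses (finite).
#' @return Factor with levels `inhibited`, `excited`.
#' @export
classifyFmi <- function(optoResponses) {
  if (any(!is.finite(optoResponses)))
    .dataError("opto responses must be finite")
  if (any(optoResponses == 0))
    warning(sum(optoResponses == 0),
            " exact-zero response(s) assigned to the inhibited group")
  out <- factor(ifelse(optoResponses > 0, "excited", "inhibited"),
                levels = c("inhibited", "excited"))
  names(out) <- names(optoResponses)
  out
}

#' Compare visual responses between opto-defined groups
#'
#' Group mean traces (+/- s.e.m. across ROIs) and a bin-level comparison
#' between the inhibited and excited groups. Since the groups are disjoint
#' neurons, the unpaired analogue of the binwise test is the default.
#'
#' @param labels Factor from [classifyFmi()], one label per tensor ROI.
#' @param tensor A [TrialTensor-class] for one stimulus condition.
#' @param window A [WindowSpec-class].
#' @param alpha,minConsecutive Binwise test parameters.
#' @param paired Use the paired binwise test (only meaningful when groups
#'   are matched; default unpaired).
#' @return List: `traces` (per group: mean/sem over relative bins),
#'   `binwise` (a [BinwiseTestResult-class]), `n` per group.
#' @export
compareGroupResponses <- function(labels, tensor,
                                  window = windowSpec(frameRate(tensor)),
                                  alpha = 0.05, minConsecutive = 3,
                                  paired = FALSE) {
  if (length(labels) != nRoi(tensor))
    .dataError("one label per tensor ROI required")
  groups <- split(seq_along(labels), labels)
  if (any(lengths(groups) == 0L)) {
    warning("empty group; comparison skipped")
    return(NULL)
  }
  if (any(lengths(groups) < 2L))
    .dataError("need at least 2 ROIs per group")
  sub <- function(idx) methods::new("TrialTensor",
    values = tensor@values[idx, , , drop = FALSE], relBins = relBins(tensor),
    trials = trialInfo(tensor), alignTo = tensor@alignTo,
    frameRate = frameRate(tensor), dropped = tensor@dropped)
  tens <- lapply(groups, sub)
  traceOf <- function(tt) {
    m <- apply(tt@values, c(1L, 3L), mean)   # ROI x relative bin
    data.frame(bin = relBins(tensor), mean = colMeans(m),
               sem = apply(m, 2L, sem))
  }
  bw <- binwiseDifferenceTest(tens[[1L]], tens[[2L]], window = window,
                              alpha = alpha, minConsecutive = minConsecutive,
                              paired = paired)
  list(traces = lapply(tens, traceOf), binwise = bw, n = lengths(groups))
}

#' Pearson correlation across ROI populations
#'
#' @param respA,respB Per-ROI means (equal length, >= 3 finite pairs).
#' @return List: `r`, `r2`, `n`; `r` is `NA` with a `reason` when either
#'   vector has zero variance (undefined, not 0).
#' @export
populationCorrelation <- function(respA, respB) {
  if (length(respA) != length(respB))
    .dataError("vectors must cover the same ROIs")
  ok <- is.finite(respA) & is.finite(respB)
  a <- respA[ok]; b <- respB[ok]
  if (length(a) < 3L) .dataError("need at least 3 ROIs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, r2 = NA_real_, n = length(a),
                reason = "zero variance: correlation undefined"))
  r <- stats::cor(a, b)
  list(r = r, r2 = r^2, n = length(a))
}

#' Pool unreinforced conditions
#'
#' For the no-reinforcement paradigm, responses are averaged across the two
#' stimulus sets: `AoVo` is the per-ROI average of `AaVa` and `AbVb`, `Vo`
#' of `Va` and `Vb`, and `Ao` of `Aa` and `Ab`.
#'
#' @param roiMeansByCondition Named list (or column-named matrix/data.frame)
#'   of per-ROI mean response vectors keyed by condition label.
#' @return data.frame with the available pooled columns (`AoVo`, `Vo`, `Ao`).
#' @export
poolUnreinforced <- function(roiMeansByCondition) {
  x <- roiMeansByCondition
  if (is.matrix(x) || is.data.frame(x))
    x <- as.list(as.data.frame(x))
  pair <- function(p, q, name) {
    if (is.null(x[[p]]) || is.null(x[[q]]))
      .dataError("pooled ", name, " requires both ", p, " and ", q)
    (x[[p]] + x[[q]]) / 2
  }
  pools <- list()
  if (!is.null(x$AaVa) || !is.null(x$AbVb))
    pools$AoVo <- pair("AaVa", "AbVb", "AoVo")
  if (!is.null(x$Va) || !is.null(x$Vb)) pools$Vo <- pair("Va", "Vb", "Vo")
  if (!is.null(x$Aa) || !is.null(x$Ab)) pools$Ao <- pair("Aa", "Ab", "Ao")
  if (!length(pools)) .dataError("no poolable condition pairs found")
  as.data.frame(pools)
}
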