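---
title: "Methods: quantifying cue-driven suppression of visual cortical responses"
author: "crossmodal package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cue-driven suppression of visual cortical responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmodal)
```

# Overview

`crossmodal` implements the analysis chain used to demonstrate that an
auditory cue, once associated with a visual stimulus, suppresses the
response of primary visual cortex to that specific stimulus. The package
has two halves that validate each other:

1. an **analysis pipeline** — ΔF/F conversion, trial alignment, windowed
   response quantification, and the comparison statistics; and
2. a **generative model** — synthetic conditioning experiments with known
   ground truth, so that every analysis-side estimate can be tested by
   parameter recovery rather than by fiat.

This vignette records the modelling assumptions, the conventions and
numerical choices that the code commits to, and what the validation does
and does not establish.

# The measurement model

## From pixels to ΔF/F

An ROI's fluorescence trace is the arithmetic mean pixel value over its
mask per frame (`extractRoiTraces()`). ΔF/F is median-normalized:
`(F − median(F)) / median(F)` over the whole recording
(`computeDff()`). The median is robust to the sparse, positive-going
transients of calcium indicators, so for recordings in which activity
occupies less than half of the frames it sits on the baseline and a
constant trace maps to an all-zero ΔF/F trace. ROIs with a non-positive
median leave the normalization undefined; they are excluded outright and
logged in the provenance. Degenerate inputs of this kind are the only
hard exclusion in the pipeline.

An optional causal exponential filter (`filterTau`, seconds) can be
applied after normalization. The default is **no smoothing**: the
upstream filter used on real recordings is acquisition-specific and its
parameters belong to the acquisition's provenance, not to this package's
defaults. Either choice is recorded in the `DffTraceSet` provenance.

## Windows, bins and alignment

All quantification windows are specified in milliseconds and converted to
frame bins by `timeToBins()`. Conventions, fixed once:

- Frames are half-open intervals `[start, start + period)`; a frame
  belongs to a window when its **centre** lies in `(start_ms, end_ms]`.
- The alignment frame (relative bin 0) is the first frame starting at or
  after the event onset.

At the 15 Hz effective rate of four-plane 60 Hz resonance scanning
(`effectiveFrameRate(60, 4)`), the response window 267–1000 ms after
visual onset comprises 11 one-frame (66.7 ms) bins and the baseline
window −667–0 ms comprises 10 bins. The per-trial scalar response is the
response-window mean minus the baseline-window mean
(`quantifyResponse()`).

For cued stimuli the baseline window lies **inside the auditory second**.
This is deliberate and matches the quantification this package
reproduces: suppression of the visual response is measured net of any
auditory-period activity. Users comparing cued and un-cued conditions
should be aware that the two baselines therefore sample different
stimulus contexts.

## The response difference index

For ROI set `i`, day `d`:
`index_i(d) = (uncued_i(d) − cued_i(d)) / norm`, with
`norm = mean_i(uncued_i(reference day))` computed once on the earliest
(reference) day and reused for all days (`indexByDay()`). The subtractive
numerator avoids per-trial division-by-zero; a zero population reference
is still fatal and raised as an error, never silently patched. The
population of per-ROI indices is compared against zero with the
normality-gated dispatcher.

## Test dispatch

`dispatchTest()` implements the normality gate: a Lilliefors test at
alpha 0.05 on the sample (on paired differences for paired/one-sample
designs); if normality is not rejected the *t*-test family is used,
otherwise the Wilcoxon family. All tests are two-sided. Two edge rules:

- samples smaller than 4 skip the normality test (it is undefined there)
  and default to the non-parametric branch, with a note in the output;
- zero-variance differences (identical samples) return `p = 1` — "no
  effect" is the only defensible answer, and erroring would make
  legitimate degenerate fixtures unusable.

## Bin-by-bin comparisons

`binwiseDifferenceTest()` compares two aligned response sets per
one-frame bin: per ROI, trial-averaged baseline-subtracted ΔF/F per bin;
per bin, a two-sided *t*-test across ROIs (paired when both sets cover
the same ROIs, unpaired for disjoint neuron groups). Bins are flagged
only within maximal runs of at least `minConsecutive = 3` consecutive
bins with `p < 0.05`; no further multiple-testing correction is applied —
the run rule **is** the correction. Degenerate bins (identical values)
yield `NA` p-values; an exactly constant non-zero difference yields
`p = 0` (the *t* statistic diverges).

A caveat that matters for interpreting the run rule: for **paired**
comparisons the per-neuron response amplitude cancels, bins are nearly
independent under the null, and the run rule suppresses false flags by
roughly two orders of magnitude (to ~0.1–0.3% per window). For
**unpaired** group comparisons the between-neuron amplitude heterogeneity
is shared across all bins of the window, bins are strongly correlated,
and the run rule's false-flag rate stays near the per-bin alpha. For this
reason the package's *decision* about a group difference (e.g. between
opto-inhibited and opto-excited neurons) is taken from the calibrated
windowed-response comparison via `dispatchTest()`, while the binwise
trace comparison is reported alongside for display, as in the original
figures.

## Optogenetic statistics

`classifyFmi()` splits neurons by the sign of their windowed response to
axon stimulation: `> 0` excited, `< 0` inhibited. Exact zeros — possible
in principle though measure-zero in practice — go to *inhibited* by a
fixed, warned tie-break so the labels always partition all neurons.
`normalizedSuppression()` uses the **population** mean response without
silencing as the default denominator (per-ROI available via
`denominator = "roi"`): the population mean is far better conditioned
when individual ROIs have near-zero responses, and the result is the
population-level fraction the figure legends quote. Positive values
denote suppression.

# The generative model

## Calcium kernel and event responses

Each 1-s stimulus drives a per-ROI response equal to its tuning amplitude
times a stimulus kernel: the boxcar convolution of a difference of
exponentials (`calciumResponse()`), with closed form
`F(t) − F(t − dur)`, `F(t) = 1 − (τ_d e^{−t/τ_d} − τ_r e^{−t/τ_r})/(τ_d − τ_r)`.
Defaults: rise 50 ms; decay 600 ms for V1 somata (GCaMP6f-like) and
1.2 s for auditory-cortex axons (GCaMP6s-like) — indicator-literature
values, since the source quantification does not pin them. The kernel is
normalized to its true peak (just after stimulus offset, located by 1-d
optimization to 1e-12), so generative amplitudes are exact peak ΔF/F
values. Kernel support is truncated where the normalized response falls
below 1e-12; this keeps event loops local and makes long-ISI zero-noise
recordings exactly baseline at the median, which is what lets the
round-trip test demand agreement with the closed-form window-gain oracle
(`windowGain()`) at 1e-9.

Suppression acts multiplicatively on the visual amplitude of the paired
cued condition only (`AaVa` uses the rewarded pairing's day factor,
`AbVb` the aversive pairing's); the day-5 recombined probe `AbVa` uses
the **unsuppressed** amplitude, which is what makes the pipeline's
specificity result recoverable. The default day profile for the rewarded
pairing is (0, 0.05, 0.15, 0.3, 0.3) — no suppression on day 1, clear
suppression by day 4 — and a weaker flat 0.1 for the aversive pairing,
reflecting its earlier, weaker and more variable time course; the
aversive profile is a user-settable parameter, not a calibrated one.

Raw fluorescence is `F0 · (1 + signal + noise)` with per-ROI baseline
`F0 ~ U(80, 120)` a.u. and i.i.d. Gaussian ΔF/F noise (default
σ = 0.1 per frame), clamped to stay strictly positive. V1 somata carry
no auditory amplitude by default — their baseline window nets out
auditory-period activity in the analysis, and giving them auditory drive
would conflate two effects in recovery tests; axons carry both auditory
and retinotopic visual amplitudes with Gaussian spatial receptive fields
(σ = 0.12 of the unit corridor extent).

## Schedules

`makeTrialSchedule()` draws per-trial conditions independently from the
configured fractions (so realized counts show binomial sampling error, as
in a real randomized design): 25% un-cued on days 1–4 and 14% on day 5,
half of un-cued trials being the never-cued control `Vc`; the recombined
probe `AbVa` appears only on day 5 at 14% of cued trials. Inter-stimulus
intervals are uniform on [4, 12] s, measured from the end of a trial's
last event to the next trial's first stimulus. Trials per day default to
120 — a ~25-minute session at these ISIs, a realistic daily yield; the
source reports fractions, not counts. Each daily session occupies its own
stretch of the recording's time axis.

## Behaviour

Anticipatory licking is per-trial Bernoulli with per-(condition, day)
probabilities; by default the rewarded pair rises (0.2, 0.3, 0.5, 0.7)
over days 1–4 while all other conditions stay flat (0.1–0.2), so day 1
shows no cued/un-cued difference and day 4 a clear one. When a trial
licks, one supra-threshold 30-ms pulse is placed uniformly **within the
anticipatory quantification window** (267–1000 ms after visual onset,
with a 20-ms margin for sample-grid rounding) rather than anywhere in the
visual second: the generative probability is then exactly the
window-lick probability the analysis recovers, which is what makes the
binomial-CI recovery test well-posed. Spontaneous licking outside trials
is not modelled. Running speed is a 10 cm/s baseline with slow
multiplicative noise and a multiplicative 30% dip during stimulus
presentation.

## Optogenetic sessions

Influence-mapping sessions drive each ROI with its signed influence
weight (`fmi_pre`/`fmi_post`) during 1-s stimulations; interleaved sham
stimulations drive an independent per-ROI response, so opto and sham are
uncorrelated by construction. In the post-learning scenario the
post-conditioning weights are negatively coupled to the `Va` amplitude
(`fmi_post = −0.06·z(vis_amp_a) + N(0, 0.05)`), enriching the inhibited
group for `Va`-responsive neurons at roughly the inhibited fraction
reported for conditioned animals (~30–50%); `Vc` tuning stays
independent, preserving the specificity control.

## Seeds

Every generator is a pure function of `(config, seed)`. A master seed
expands into named child streams (`childSeed(seed, "neural")`, ...) so
schedule, neural, behaviour and opto generation can be re-run
independently without perturbing one another.

# Validation strategy and problem sizes

The package's empirical claims are exactly the ones its tests and
`scripts/acceptance.R` compute:

- **Window arithmetic** is checked exactly (11/10 bins, 66.7-ms bins,
  15 Hz per plane).
- **Oracle equivalence**: windowed responses, the index, normalized
  suppression and correlations agree with naive-loop recomputations to
  1e-12.
- **Round trip**: rendering a zero-noise movie, extracting, normalizing,
  aligning and quantifying recovers amplitude × window-gain to machine
  precision (the test uses long ISIs so the median sits on the exact
  baseline).
- **Parameter recovery**: with generative suppression in {0, 0.15, 0.3}
  (500 ROIs, 40 trials per condition, 20 replicates), the mean estimated
  index lands within ±0.05 of truth (observed |bias| < 0.002) and is
  strictly monotone in truth.
- **Type-I control**: on 1000 no-effect replicates of 200 ROIs the
  one-sample index test rejects at 0.05 ± Monte-Carlo error, and the
  ≥3-consecutive-bin flag rate matches a brute-force simulation of the
  null model (per-bin values with the analytically known shared-baseline
  covariance) and sits near the exact independent-bin run probability
  (~0.1%). These null replicates are drawn at the statistic level — from
  the generative model's implied response distributions — because
  trace-level simulation at this replicate count adds cost but no
  statistical content; trace-level nulls are exercised separately at
  smaller n elsewhere in the suite.
- **Selectivity recovery**: in 50 post-learning replicates (563 neurons,
  matching the mapped population size) the inhibited/excited comparison
  detects a `Va` difference in ≥95% of replicates while `Vc` detections
  stay within the Monte-Carlo envelope of the 5% test level; pre-learning
  replicates stay at the null level for both. (A null comparison can
  never report "no difference" in more than 1 − alpha of replicates in
  expectation; the envelope is the statistically meaningful reading.)
- **Receptive fields**: with the default 20×8 grid and 5 presentations
  per position, ≥90% of simulated axons (observed 95%) have their map
  peak within one grid step of the generative centre at default SNR.
- **Behaviour**: lick-trial fractions from 10 simulated mice × 4 days ×
  120 trials recover the generative probabilities within binomial CIs,
  with the cued > un-cued difference detected on day 4 but not day 1.

These sizes keep the complete suite and the acceptance script each within
a few minutes on one CPU while leaving all Monte-Carlo envelopes tight
enough to be meaningful.

# What passing these tests does not show

The generator is a measurement model, not a cortical model. Real
recordings contain motion artifacts, neuropil contamination, correlated
(shared) noise across neurons, bursty licking, reward-consumption
licking, slow drift, and day-to-day population turnover — none of which
are simulated, and the first two are explicitly out of scope (masks and
motion-corrected movies are inputs). Passing recovery tests shows the
*analysis* is correct and calibrated under the stated noise model; it
cannot certify performance under artifacts the model omits. Auditory
responses in V1 somata are zero by construction, so the package's
recovery results do not probe how auditory-period baseline activity
interacts with the index — with real data that interaction is handled,
as here, by the baseline window sitting inside the auditory second.
Anesthetized recordings are represented only as a visual-amplitude scale
factor (0.1), reproducing the near-absence of visual responses
qualitatively, with no mechanism implied.

# Known limitations

- Positions in the virtual corridor are abstract coordinates; the
  mapping to degrees of visual angle is rig-specific and out of scope.
- The ΔF/F smoothing filter used upstream of the original analysis is
  cited, not specified; it is exposed as configuration and off by
  default.
- Whether one or several trials are removed per speed-matching iteration
  is not specified upstream; this package removes one per group per
  iteration (the minimal reading) and logs every removal.
- Responsive-ROI classification uses a paired across-trials test of
  response vs baseline windows (threshold-free); a fixed-threshold
  variant is not implemented.
- `runAnalyze()` sequences the single-session analyses; multi-animal
  aggregation beyond licking (mean ± s.e.m. across mice) is left to the
  caller, with the aggregation unit carried as mandatory metadata.
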