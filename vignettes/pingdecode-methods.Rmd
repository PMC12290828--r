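---
title: "Models and methods behind pingdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pingdecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pingdecode)
```

`pingdecode` implements the analysis chain of a cued-recall EEG
experiment in which brief visual impulses (pings) are presented during
retrieval to test whether they regularize neural dynamics and thereby
improve the multivariate readout of retrieved image categories. This
vignette documents the underlying models, the parameters that matter,
the numerical choices made where the procedure was genuinely open, and
what the synthetic-data results do and do not establish.

## The experimental design model

`generate_design()` reproduces the experiment's combinatorics: 8 blocks,
10 verb–image pairs per block encoded once, each pair recalled 4 times,
i.e. 320 recall and 80 encoding trials. Images are drawn from a nested
category hierarchy (2 top x 2 middle x 4 bottom x 12 instances = 192
leaves) with equal numbers of objects and scenes per block.

Two constraints are stated for the recall phase: 75 % of trials carry a
ping (uniform within the early 500–833.33, middle 833.34–1116.67, or
late 1116.68–1500 ms SOA bin) and object/scene categories are balanced
within every condition. The published description leaves open whether
conditions were balanced within pair or only within block; we allocate
each pair's four repetitions one-each to early/middle/late/none, the
simplest rule that forces both stated constraints simultaneously. Trial
order within a block is a uniform random permutation, rejected and
redrawn until no pair occurs twice in a row.

`make_pseudo_pings()` assigns each no-ping trial a time drawn from the
pool of that design's real ping times. Sampling is with replacement, per
trial: the description is silent on replacement, and with-replacement
draws keep pseudo-ping times i.i.d. from the empirical ping-time law.

## The signal model

`simulate_epochs()` generates, per trial, the sum of:

* **1/f noise** — spectrum `|X(f)| ∝ f^(-exponent/2)` with random phases
  (exponent 1, RMS 10 µV per channel by default), the standard broadband
  EEG background;
* **an oscillation** — 10 Hz, 5 µV, random phase per trial and channel,
  so that band-power features see realistic narrowband energy;
* **a ping-evoked response** on ping trials — a biphasic kernel
  (Gaussian positive lobe peaking 250 ms after the ping, followed by a
  shallower negative rebound) weighted 1 on posterior channels and 0.2
  elsewhere, matching the observed posterior 200–300 ms evoked peak;
* **a category pattern** — a fixed unit-norm channel weight vector per
  class (drawn once per participant from a seeded substream), scaled by
  `effect_uv` (default 2 µV) and a half-cosine envelope of 300 ms,
  starting at an onset drawn from
  `Normal(onset_mean, jitter_sd * (1 - rho * is_ping))`.

The last line is the package's operationalization of the hypothesis
under study: `rho = 0` means pings leave trial-to-trial latency jitter
untouched; `rho = 1` means pinged trials are perfectly aligned. This is
deliberately the *simplest* model exhibiting the latency-jitter
pathology — real reinstatement is not a fixed spatial pattern with a
smooth envelope, jitter is unlikely to be Gaussian, and pings surely do
not affect latency without affecting amplitude. Consequences for
interpretation: passing tests show the *statistical machinery* is
calibrated and sensitive to the mechanism as modelled; they say nothing
about whether real pings regularize real dynamics.

Every stochastic stage draws from a named substream of the master seed
(design, pattern, latency, noise), so e.g. changing the latency model
never perturbs the noise realization.

## Features

Voltage features follow the published pipeline: baseline correction
(mean over the half-open `[-200, 0)` ms window), Gaussian-weighted
moving average (140 ms window, 20 ms steps, yielding a 50 Hz decoding
time course), and per-(trial, window) z-scoring across channels with the
population (n) denominator.

Two numerical choices deserve a note:

* **Kernel width.** The operational definition is that the centre
  sample is weighted 1 and the tail samples 0.15; sigma follows from
  `exp(-e²/2σ²) = 0.15` with `e` the offset of the window's edge sample
  (68 ms at 250 Hz), giving σ ≈ 34.9 ms and a realized FWHM of 82.2 ms.
  A nominal FWHM of "about 81 ms" is mutually inconsistent with the
  tail-weight rule at this discretization; the tail weight is treated as
  the definition, and the realized FWHM is reported on the result
  (`fwhm_ms`).
* **Window placement.** Windows slide from the first fully covered
  position in integer-sample steps, so the output count is exactly
  `floor((n_samples - window_samples)/step_samples) + 1` and window
  centres are spaced `step_ms` apart. Only fully covered windows are
  emitted. (An alternative convention pins centres to multiples of
  `step_ms` relative to the lock; the two differ by at most one window
  and the count rule above is the one we keep, since it is invariant to
  where the epoch happens to start.)

Zero-variance feature vectors (possible in degenerate synthetic input)
z-score to zeros with a warning rather than NaN, so a flat channel
cannot poison downstream stages.

Band-power features band-pass filter (zero-phase two-pass Butterworth,
order 4 — the source scripts' filter family is not stated, so the order
and family are configurable), take the analytic-signal envelope via the
FFT-based Hilbert transform, square it, and then reuse the voltage
windowing/z-scoring path. A pure 10 Hz sinusoid of amplitude A recovers
alpha power A² to within 5 % mid-epoch, which is the accuracy limit set
by filter ripple and edge transients.

## Decoding

The classifier is a linear discriminant with Ledoit–Wolf shrinkage of
the pooled within-class covariance toward a scaled identity. Shrinkage
is automatic (the publication does not state a regularization; with up
to 64 channels and as few as 60 training trials some regularization is
necessary, and Ledoit–Wolf is the standard parameter-free choice).
Cross-validation is stratified 5-fold with 25 repetitions, fold
assignment reseeded per repetition; binary problems are scored by the
rank-based (Mann–Whitney) AUC, multiclass by accuracy with the chance
level `1/n_classes` carried on the result so that levels with different
class counts can be compared on a common footing.

First-level null distributions come from decoding with shuffled labels
(100 shuffles x 3 CV repetitions by default). Cross-phase
generalization trains one classifier on all encoding windows with
centres in 100–1000 ms; each (trial, window) sample enters as an
independent training instance ("pooling"), which preserves the temporal
variance of the training data. Window-averaging is available as an
option (`pool = "average"`), since the source text does not disambiguate
the two readings.

Level selection decodes each hierarchy level on no-ping trials, compares
empirical accuracy against the participant-mean shuffled accuracy with a
per-window Wilcoxon signed-rank test (Benjamini–Yekutieli corrected),
and selects the level with the most significant windows; ties break
toward the largest chance-normalized peak accuracy
`(acc - chance)/(1 - chance)`, then toward the coarser level (more
trials per class).

## Group statistics

The two-level Monte-Carlo permutation test builds, per window, a null
distribution of group-mean decodability: each of `n_second_level`
(default 10^5) draws samples one first-level shuffled value per
participant, with replacement, and averages them. P-values use the
add-one convention `p = (1 + #{null ≥ observed})/(n + 1)`, which can
never return zero and is valid for any number of draws; the published
percentile-based mapping does not state its tie- and zero-handling, and
add-one is the conservative resolution. Window restriction (0–500 ms
ping-locked, 500–2000 ms cue-locked) is applied *before* FDR correction
so the correction spans exactly the tested windows. FDR uses
Benjamini–Yekutieli (`p.adjust(method = "BY")`), the variant valid under
arbitrary dependence, as decoding windows are strongly autocorrelated.

The Wilcoxon signed-rank contrast is exact when feasible (n ≤ 25, no
ties or zeros) and otherwise uses the normal approximation with
continuity correction; windows where every paired difference is zero get
p = 1 with a warning.

## The peak-order-distance test

For each participant, one peak latency is extracted from each of the
early/middle/late decoding time courses, the latencies are ranked
(latency ties break by condition order, early < middle < late), and

```
POD_raw  = sum_i |rank(peak_i) - i|,     POD = POD_raw / 4,
```

where 4 is the maximum of `POD_raw` over the six orderings of three
peaks (attained by three of them; brute-force enumeration is part of the
test suite). The default peak detector takes the cumulative sum of the
series and the argmax of its central-difference derivative. Analytically
the derivative of a cumulative sum is the series itself; with *central*
differences the operator becomes a two-point moving average, which is
the only reading under which the construction differs from a raw argmax.
It is exposed as one detector among four (`cumsum_deriv`, `argmax`,
`smoothed_argmax`, `centroid`), and `detector_benchmark()` measures each
detector's type-I error and power on simulated peak-order data.

The group statistic is the across-participant mean normalized POD,
tested left-sided (ordered peaks → small POD) against second-level draws
that assign every participant one shuffled time course per condition
from that participant-and-condition's first-level pool (the shuffled
decoders are condition-specific, so the pools are kept per condition).
The default is 10^6 draws, computed in chunks with precomputed pool peak
latencies so the full-scale test runs in seconds.

One property of this statistic matters for calibration checks:
per-participant POD takes only the values {0, ½, 1}, so the group mean
is discrete and the non-strict add-one p-value includes the full tie
mass, making it slightly *conservative* (never anticonservative). Null
simulations in the test suite therefore check uniformity with a
one-sided Kolmogorov–Smirnov test against anticonservative deviation
plus a binomial envelope on the rejection rate, rather than demanding
exact uniformity from an intrinsically discrete statistic.

## ERP analyses

ERP traces are zero-phase 0.2–40 Hz filtered, baseline-corrected
(-200–0 ms), averaged per condition, and summarized over the standard
posterior channel set. The ping vs pseudo-ping contrast averages each
participant's 200–400 ms post-event amplitude per channel and permutes
at the *participant* level (random sign flips of the paired difference,
10^5 randomizations, Bonferroni over channels). The publication does not
state the exchangeability unit of its Monte-Carlo test; participant-level
sign flipping is the standard group-level choice and keeps the test
exact under the paired design.

## Problem sizes used for validation

The validation suite runs every stochastic study at a reduced scale
chosen to keep the full suite in the tens of minutes on one core while
leaving each check well-powered; the full-scale defaults (25 CV
repetitions, 100 shuffles, 10^5/10^6 second-level draws) remain the
package defaults. Specifically: null calibration uses 200 replicate
effect-free datasets of 20 participants x 80 trials x 16 channels with
short epochs (5 decoding windows), 10 label shuffles and 2000
second-level draws; POD power uses 10 replicate 20-participant groups
with SOA-ordered onsets at high SNR (8 µV pattern on 5 µV noise) and
10^4 draws; the trial-count study uses the grid 40/120/240 trials with
11 replicates of 8 participants per cell and a 5 µV effect, a moderate
amplitude chosen so the 40-trial cell is detectably but not saturatedly
significant; the latency-regularization contrast uses 20 participants
with 150 ms jitter and rho = 1.

## Known limitations

* The generator emulates the design and the latency-jitter mechanism,
  not real EEG: no artefacts, no cap-geometry forward model, no
  Laplacian re-referencing (the simulator emits pattern data directly),
  no behavioural responses.
* The LDA is the only classifier; non-linear decoders and temporal
  generalization matrices are out of scope.
* Cluster-based permutation statistics are intentionally absent; the
  per-window Wilcoxon/FDR route is the package's inference path.
* Epoch and feature containers are stored as documented RDS files (CSV
  for all tables, YAML/JSON for configs); no BrainVision or other raw
  EEG formats are read.
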