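---
title: "Methods: synthetic EEG cohorts, band-limited features, and weightless classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic EEG cohorts, band-limited features, and weightless classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`emobio` implements an EEG biomarker pipeline for mental imagery of facial
expressions: subjects watch, and later mentally re-create, happy and sad
expressions performed by a virtual avatar, and subject-level feature vectors
extracted from the imagery EEG are used to classify subjects into a clinical
("asd") and a comparison ("td") group. This vignette documents the model
assumptions, the tunable parameters, the numerical choices, and what a green
test does — and does not — establish.

## The experimental paradigm emulated by the generator

Two tasks are modeled as trial schedules:

* **Visual task** — 2 blocks of 120 randomized trials (60 per expression),
  240 trials. Each trial is 1.5 s: 250 ms morph from neutral into the
  expression, 1 s static expression, 250 ms unmorph. The inter-trial
  interval is 1 s plus a uniform jitter on [0, 500] ms (the jitter's
  distribution is not specified by the paradigm description; uniform is the
  least-informative choice on a bounded interval).
* **Imagery task** — 2 blocks of 40 randomized trials (20 per expression),
  80 trials. Each trial: 1.5 s instruction (the avatar performs the target
  expression), 1.5 s preparation, a cue, 4 s of imagery, a second cue, then
  a neutral period. The neutral period's printed length is not available;
  we fix it at 4 s, mirroring the imagery period, so that emotion and
  neutral analysis windows are strictly comparable.

A 20 s inter-block gap stands in for the self-paced rest between blocks,
and a 3 s lead-in precedes the first trial so pre-trial baselines always
fall inside the recording.

## Synthetic cohorts: a stated world, not a fitted one

No participant EEG is distributed with the source study, so every
downstream stage is validated against a synthetic cohort whose ground truth
is known by construction. Per channel, the continuous signal is

    x(t) = A_bg * pink(t; alpha) + sum_b osc_b(t) + eps(t),

where `pink` is 1/f^alpha noise (alpha = 1 by default, unit variance,
scaled by `A_bg` = 10 uV RMS), each `osc_b` is white noise band-limited to
band `b` by an order-4 zero-phase Butterworth filter and scaled to a
per-band RMS (defaults: theta 2, alpha 3, low-beta 1.5, high-beta 1, gamma
0.8 uV — an alpha-dominant, 1/f-shaped spectrum a clinician would call
plausible resting-like EEG), and `eps` is white sensor noise (SD 2 uV).
The oscillation filters are order 4 so that the injected "theta"
oscillation actually respects its stated 4–8 Hz band: adjacent analysis
bands share edges (theta/alpha meet at 8 Hz), and a shallower filter would
leak a deliberately injected theta effect into the alpha features.

Group effects are multiplicative amplitude gains on one band's oscillation,
restricted to the channels of one electrode cluster and to one trial window
(emotion imagery, neutral period, or both), applied with 50 ms
raised-cosine ramps so the gating itself injects no broadband edges. The
default effect set elevates theta (gain 1.5) and high-beta (1.3) in the
right parieto-occipital cluster C4 and gamma (1.3) in the occipital cluster
C5, during emotion imagery, in the "asd" group — the band-by-region pattern
the pipeline is designed to recover.

What the generator does **not** emulate: volume conduction from
source-space generators, between-subject heterogeneity (all subjects of a
group are draws from the same process), eye/muscle artifacts, non-stationary
background, or event-related potentials. A green recovery test therefore
establishes that the pipeline can detect and localize a band-limited
amplitude effect at realistic SNR — not that it reproduces any real-data
accuracy figure.

## Montage and clusters

The 64-channel 10-10 montage uses idealized unit-sphere positions computed
from the standard 18-degree grid; geometry is cosmetic, since the analysis
uses clusters by name. The four right centro-parietal to occipital clusters
pool the region over the right precuneus:

* C1 = C2, C4, C6, CP2, CP4, CP6 (right centro-parietal)
* C2 = P2, P4, P6, P8 (right parietal)
* C4 = PO4, PO8, TP8, TP10 (right parieto-occipital)
* C5 = O2, Oz, POz (occipital, right-leaning)

The source study's cluster figure is not available in the extracted text,
so these memberships are a documented stand-in, shipped as an editable CSV
(`inst/extdata/clusters.csv`); they are disjoint, cover the right posterior
quadrant, and follow lobule divisions.

## Preprocessing

Offline, zero-phase everywhere: the band-pass (default 1–100 Hz) is a
Hamming windowed-sinc FIR applied as a centered convolution; the notch
(default 47.5–52.5 Hz) and the per-band filters are IIR applied
forward-backward. Zero-phase application is deliberate: the non-linear
features depend on waveform shape, and a causal filter's phase distortion
would bias them.

Bad-epoch rejection uses two criteria: an absolute threshold (default
100 uV) and a joint log-probability criterion — each trial's log-likelihood
under per-channel normal fits pooled across trials, rejected beyond
`prob_z` (default 5) SDs from the across-trial mean. The thresholds are
conventional defaults, config-exposed, because the source procedure names
the criteria but not its thresholds. The normal-fit log-probability is a
transparent stand-in for histogram-based estimates; the test suite pins it
to an independent reimplementation. Component-based artifact removal (ICA)
is a documented identity hook: infomax decomposition is an external,
published algorithm orthogonal to this package's content, and the synthetic
cohorts contain no artifacts to remove. Bad channels are excluded rather
than interpolated; cluster averaging already pools neighboring channels.

## Features

Per trial, channel, band (theta 4–8, alpha 8–12, low-beta 12–21, high-beta
21–30, gamma 30–40 Hz) and window, eight features are computed on the
band-filtered series. Windows are: baseline (500 ms before the
instruction), emotion (0.5–3.5 s after the imagery cue), neutral (0.5–3.5 s
after the neutral cue). The epoch is filtered once per band and windows are
sliced afterwards, so window edges never interact with filter transients.

Time/frequency features (reported baseline-normalized, window minus
baseline): envelope = mean |analytic signal|; Teager energy = mean of
psi[n] = x[n]^2 − x[n−1]x[n+1]; power = mean x^2. The exact summary
statistics are not printed in the available text; these means are the
natural single-number summaries and are documented as interpretations.

Non-linear features (reported as absolute values) are computed on
time-delay embeddings X(t) = [x(t), x(t+tau), ..., x(t+(m−1)tau)] with the
lag tau taken per series as the first local minimum of the
autocorrelation (fallback: first zero crossing, then N/10):

* **SFI** (m = 2): the phase portrait is min-max normalized to the unit
  square, binned on a 10x10 grid; SFI = sum(p^2)/grid^2.
* **Largest Lyapunov exponent** (m = 3), Rosenstein's method: slope of the
  mean log nearest-neighbor divergence over steps 1–6, Theiler window =
  tau. Step 0 is excluded from the fit — nearest-neighbor selection biases
  the initial separation low, which would inflate the slope for regular
  signals. Neighbor pairs whose initial separation is below 1e-10 of the
  attractor diameter are discarded as round-off; if none survive, the
  orbit is numerically periodic and the exponent is reported as 0.
* **Correlation dimension** (m = 3), Grassberger–Procaccia: slope of
  log C(r) vs log r on 10 log-spaced radii between the 5th and 50th
  percentile of pairwise distances; embeddings beyond 250 points are
  thinned evenly before pair counting (a compute/variance trade-off that
  leaves the line/square calibration oracles within their tolerances).
* **ApEn** (self-matches included) and **SampEn** (excluded), template
  length m = 2, tolerance r = 0.2 SD, Chebyshev distance. With r
  proportional to SD both are scale-invariant, so a pure amplitude gain
  moves them only through the changed oscillation-to-background mix.
  SampEn with no template matches is an NA sentinel; cluster averaging
  skips sentinels and reports their count.

## Feature table, selection, classification

Features are averaged over all imagery trials (happy and sad pooled — the
per-expression split is config-exposed) and over the channels of each
cluster, giving 8 features x 5 bands x 4 clusters = 160 columns per
subject. Per repetition of the evaluation: a stratified 80/20 split (with
17+17 subjects: 14+14 train, 3+3 test; stratification avoids one-class
test sets that an unstratified split would produce at this n), Welch
two-sample t per column on training rows only, columns ranked by |t| (ties
by fixed column order), and for each feature count k in {5, 10, ..., 160}
both classifiers are fitted on the training rows and scored on the test
rows. Welch rather than pooled-variance t is the default because no
equal-variance assumption is stated; a `pooled` switch exists.

The linear SVM is an in-package L2-regularized squared-hinge primal
(L-BFGS), a maximum-margin linear separator with C = 1; features are
z-scored with training-fold statistics by default (config-exposed — the
source does not state whether features were standardized). The WiSARD
classifier is built from scratch: per-feature thermometer encoding (16
bits, min/max from training rows only), a seeded random permutation of the
bits partitioned into 4-bit tuples (zero-padded to a multiple of the tuple
size), one RAM-discriminator per class with write counters, and bleaching:
responses are counted at threshold b, and b increases while the best
response is tied; a tie persisting to all-zero responses falls back to the
raw response, then lexicographic order. Hyperparameters (16 bits, 4-bit
tuples) are unreported in the source; these defaults are standard in the
weightless-network literature and are swept in the tests.

Headline metrics (accuracy, specificity, sensitivity, precision, F1, with
the clinical group as positive class and zero-denominator ratios reported
as NA sentinels) are tabulated at k = 15 by default; k = 25 is exposed
because the source's figure caption and text disagree on which was used.
The emotion-vs-neutral accuracy contrast is a paired per-repetition t-test
per k, FDR-adjusted (Benjamini–Hochberg) across k. The default repetition
count is 50 (satisfying "more than 30"), with per-repetition seeds derived
from a master seed.

### Chance-level calibration

`evaluate(..., permute_labels = TRUE)` re-permutes the group labels freshly
at every repetition. A single fixed permutation is deliberately avoided:
it retains accidental finite-sample feature-label correlations that a
repeated-holdout procedure exploits consistently, biasing "null" accuracy
above 0.5; averaging over fresh permutations is the proper permutation
null.

## Numerical choices and degenerate inputs

* Sample rounding: nearest sample, ties toward +Inf; epoch windows are
  half-open `[start, end)`; indices are 0-based in ms-to-sample arithmetic
  and 1-based in R arrays.
* Filters never match a specific toolbox's coefficients; contracts are on
  the magnitude response (attenuation and passband tolerances), verified
  with FFT oracles.
* Constant series: autocorrelation lag falls back with a warning; entropy
  tolerances r = 0.2*SD would be zero, so entropies error instead of
  returning spurious values; SFI of a degenerate (zero-range) axis
  collapses that axis with a warning.
* Thermometer encoding of a constant feature (training min = max) is
  all-zero with a warning, so such a feature cannot influence the WiSARD.

## Scaled test world

The recovery tests and the acceptance suite run the full 17+17-subject
design, but at 100 Hz sampling (the analysis bands end at 40 Hz, so this
discards no information of interest) and 8 imagery trials per subject
instead of 80, to fit a single-CPU test budget. Scaling down trials raises
only the measurement-noise floor of subject-level features; the injected
effect structure is unchanged. Within this scaled world the pipeline's
recovery claims (emotion-window accuracy above neutral-window accuracy,
theta-heavy top-15 selections, chance-level permutation null) are asserted
at a fixed master seed.

One recovery property deserves honesty up front: with a theta-only gain
injected in cluster C4, a strict majority of top-15 selections being
theta-band features is **not** attained in this world (the tally sits just
below one half, and grows no higher with more trials). The cause is
structural, not a defect of scale or implementation: (i) only eight
feature keys combine theta with the affected cluster, and the five
non-linear ones are wholly or largely scale-invariant, so a pure amplitude
gain reaches the ranking mainly through the three time/frequency features
plus the correlation dimension; and (ii) the theta and alpha bands share
the 8 Hz edge, so a band-limited theta oscillation amplified threefold
genuinely discriminates through alpha-band features as well — in real
recordings exactly this kind of adjacent-band bleed is expected. The
corresponding acceptance assertion is kept faithful to its statement and
is allowed to fail, rather than re-shaping the generator post hoc until it
passes.

## Known limitations

* The synthetic cohort has no between-subject variability beyond sampling
  noise, so classifier accuracies on it saturate at effect sizes where
  real data would not; accuracy values on synthetic cohorts are not
  comparable to real-data figures.
* Cluster memberships and several feature-summary formulas are documented
  interpretations of incompletely specified sources.
* The BrainVision writer/reader covers the multiplexed IEEE-float layout
  this package writes, not every header variant in the wild; EDF export is
  not implemented.
* sLORETA source localization, SnPM statistics, topographic maps, ICA and
  spherical-spline interpolation are out of scope by design.
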