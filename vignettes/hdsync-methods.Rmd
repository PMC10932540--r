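---
title: "Models and methods behind hdsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hdsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hdsync` implements an analysis chain for paired-region head-direction (HD)
recordings: HD-cell selection, population decoding of heading, cue-rotation
realignment and lag analysis, darkness drift correlation, spike-train
connectivity, and waveform-based cell typing. This vignette documents the
models, their assumptions, every tunable that matters, and the places where
the design was genuinely open and a choice had to be made.

## Angular conventions

All user-facing angles are degrees; positive rotations are
counterclockwise. Wrapped differences live in `(-180, 180]`, with the
boundary mapped to `+180` (`wrap_diff(180, 0)` and `wrap_diff(0, 180)` are
both `+180`). Circular means, resultants and the Rayleigh test follow the
standard first-trigonometric-moment definitions; the circular-circular
correlation is the Fisher–Lee estimator
ρ = Σ sin(x−x̄) sin(y−ȳ) / √(Σ sin²(x−x̄) Σ sin²(y−ȳ)), which is invariant
to rotating either variable. Where an analysis needs a concentration
parameter from a curve rather than a fit, κ is obtained by inverting the
von Mises A1 function at the observed resultant.

## Tuning curves and HD-cell selection

A tuning curve is the spike histogram over 36 half-open 10° heading bins
divided by occupancy, with spikes assigned to their nearest 50 Hz tracking
sample. This makes the accounting exact — `sum(rate * occupancy)` equals
the spike count — which the tests assert to machine precision. Zero-occupancy
bins carry `NA` rates and are excluded downstream.

*Smoothing.* The smoothing kernel is a circular Gaussian with SD one bin
(10°), applied to counts and occupancy separately and re-divided, so the
spike mass is preserved exactly. The kernel is defined spectrally (Fourier
coefficients `exp(-(kσ)²/2)`), which makes the Gaussian semigroup hold
exactly — smoothing twice at σ equals once at σ√2 — at the cost of
occasional tiny negative ringing on near-delta curves; weighted circular
means clamp weights at zero for this reason. The SD is a free parameter
(`sigma_bins`) because the choice is conventional, not principled.

*Selection.* A unit is an HD cell when directional information (bits/spike),
resultant length, and concentration all exceed the 98th percentile of 500
shuffles on **two** distinct stable cue-on segments. Shuffles circularly
time-shift the whole spike train within the segment by uniform amounts at
least 20 s from either end; 20 s is our choice of minimum shift — large
enough to destroy spike–heading alignment at typical mouse head-turn
timescales — and is configurable. Information and resultant are computed on
the raw curve and concentration on the smoothed curve (or, for multi-peak
units, from the largest peak of the von Mises fit), and the shuffle
distribution mirrors whichever path the real metric takes. Units with no
spikes or with fewer than 33 of 36 bins at ≥ 1 s occupancy are
*unclassifiable*, a third label deliberately distinct from non-HD.

*Peaks and fits.* Peak counting uses circular local maxima constrained by
minimum circular distance 120°, minimum width 40° at half prominence, and
prominence strictly greater than 11 — prominence read in Hz, since the rates
being thresholded are in Hz. The von Mises model
λ(θ) = c₁ + Σₖ c₂ₖ·e^{c₄ₖ cos(θ−c₃ₖ)}/(2π I₀(c₄ₖ)) (1–3 peaks) is fit by
Levenberg–Marquardt with peak locations/heights initialized from the peak
finder and the offset at 0; κ is bounded to [0, 500] and the Bessel factor
uses the exponentially scaled form for numerical stability. Non-convergence
is flagged, and flagged units are excluded from the concentration criterion
rather than failed.

*Angular velocity* is the first difference of the unwrapped heading
decimated to 500 ms, re-interpolated linearly to 50 Hz. The 500 ms
decimation suppresses tracking jitter; the 30°/s cutoff used to split
analysis epochs into low/high angular velocity is the conventional value
for mouse head turns.

## Decoding

The decoder is a linear-Gaussian model from population rates to the sine
and cosine of heading:

1. 20 ms binned rates per unit;
2. zero-phase Butterworth low-pass, order 3, normalized cutoff 0.2;
3. z-scoring per unit with training-window statistics only (zero-variance
   units are dropped with a warning);
4. two ridge regressions (shared penalty λ, default 1.0 on the z-scored
   predictors) onto sin θ and cos θ, with the target angle quantized to 10°
   bin centers;
5. decoded heading = atan2(ŝ, ĉ).

Three parameters deserve comment because the procedure leaves them open.
The **filter order and phase** are not dictated by the model; we use order
3 and, critically, zero-phase (forward–backward) filtering, because any
causal filter would delay every decoded trajectory by a fixed lag and
contaminate the inter-regional lag analysis with an artifact of the
pipeline. The **ridge penalty** defaults to 1.0 on z-scored predictors —
with ≥ 120 s of training data the fit is insensitive over orders of
magnitude, and the value is exposed. The **10° quantization** is applied to
the regression targets (the predictors stay continuous rates); quantizing
the targets rather than the outputs reproduces a decoder whose codomain is
the binned heading, and the ambiguity is noted here because the alternative
reading (binning the decoded output) differs by less than half a bin.

The **decoded error** is the wrapped difference *tracked − decoded*. The
sign matters: when the internal reference (and with it every cell's
preferred direction) rotates by +Δ, a decoder trained before the rotation
reports headings Δ behind the world, and tracked − decoded = +Δ. With this
convention the decoded rotation (circular mean error after minus before)
and the tuning-curve ensemble rotation estimate the same quantity with the
same sign, which the tests verify to ±15°.

*Accuracy and the shuffle gate.* Accuracy is the median absolute decoded
error. A session is used for coordination analyses only if its accuracy
beats the 10th percentile of 100 decoders trained and tested after
circularly shifting each unit's spike train by an independent random
amount. By construction this gate admits ≈ 10% of truly uninformative
sessions (the real statistic is exchangeable with its shuffles when there
is no heading signal); it is a screen against uninformative ensembles, not
a hypothesis test with a controlled false-omission rate.

## Coordination analyses

*Rotation trials.* Per-unit PFD shifts are computed from smoothed tuning
curves in pre- and post-rotation windows, with a 1 s minimum per-bin
occupancy gate in both windows. Ensemble rotation is their circular mean
(SEM from the circular SD). Significance uses a per-unit null built by
reassigning tracking-sample indices between the pre and post windows 500
times; a trial is significant when at least half the units (boundary
inclusive) exceed their own 98th-percentile null shift magnitude. Pairwise
rigidity correlates the pairwise PFD differences before vs after rotation
across all unique pairs.

*Lag analysis.* Paired decoded-error traces are unwrapped **within the
analysis window only** (75 s after rotations, 25 s for the short variant),
mean-removed, and cross-correlated (Pearson, truncated overlap) over ±5 s
in 20 ms steps. Whether to unwrap and demean is an interpretation — wrapped
traces with a reference sitting near ±180° would produce spurious jumps, so
we unwrap, but confine the unwrap to the short window to avoid
accumulating branch errors. Ties at the peak resolve to the smallest
absolute lag, negative before positive. The null distribution of peak lags
comes from 100 circular shifts of the region-B trace (minimum shift 10 s),
and observed-vs-null peak-lag distributions are compared with a two-sample
Kolmogorov–Smirnov test. Positive lag means region A leads. The lagged
difference profile — median over 7 non-overlapping 5 s segments of the
absolute per-segment median wrapped difference — cross-checks the
correlation analysis with a statistic that is robust to slow jitter; for
error differences the trial rotations are sign-aligned first.

*Darkness drift.* Decoded errors are averaged (circular mean) over 2-min
bins that never straddle a cue on/off change; coordination is the circular
correlation of the two regions' bin series — overall, per cue state, and
within low/high angular-velocity samples (cutoff 30°/s, applied
sample-wise before bin averaging). The null band comes from 100 circular
shifts of the region-B series. The 2-D histogram of paired drifts uses 10°
bins and is normalized by each column's maximum, columns being the
region-A axis.

## Connectivity

Cross-correlograms (CCGs) count all spike-pair lags t_post − t_pre in
0.5 ms bins over ±50 ms. The ±50 ms extent is our choice (wide enough for
a stable convolved baseline; only 1–5 ms is ever tested). Lags are rounded
to a 10 µs grid before binning — immaterial against 0.5 ms bins, but it
makes the histogram exactly invariant under joint time translation of both
trains, which is asserted in the tests.

The baseline "homogeneous firing" correlogram is the CCG convolved with a
10 ms-SD Gaussian. The convolution is **not** hollow (the central bins'
own mass is included); a hollow variant is available via `hollow = TRUE`
since both conventions exist in the literature. Reflection padding at the
edges keeps flat correlograms exactly flat and conserves total mass.

Detection: in the eight bins with lags in (1, 5] ms, a bin is significant
when its count exceeds the 99.9th percentile of the cumulative Poisson
distribution at its baseline rate (count > qpois(0.999, baseline), i.e. a
strictly-above rule); a putative excitatory connection requires at least
two consecutive significant bins, and its latency is the lag of the
highest-count qualifying bin. The census tests both directions per pair
(A→B at positive lags, B→A at negative), tabulates connections by
direction, HD class and RS/FS class, and summarizes the PFD differences of
connected HD–HD pairs (circular mean/SD, Rayleigh test) against matched
non-connected partners of the same presynaptic units.

## Waveform classification

The mean waveform is spline-interpolated to a 0.01 ms grid and polarity-
normalized so the spike's dominant deflection is negative. Peak-to-trough
is the time from that deflection to the maximum of the
afterhyperpolarization; symmetry is (post-max − pre-max)/(post-max +
pre-max). Units are RS when peak-to-trough is strictly greater than
0.42 ms, FS otherwise — the boundary itself classifies as FS, a convention
the tests pin down.

## The synthetic session generator

The generator produces the statistical structure the analyses assume, with
complete ground truth:

* **Heading**: angular velocity is an Ornstein–Uhlenbeck process
  (stationary SD 45°/s, relaxation 0.5 s — freely-moving-mouse-like head
  kinematics), integrated at 1 kHz and exported at 50 Hz.
* **Units**: von Mises-tuned inhomogeneous Poisson units,
  λ(t) = base + peak·exp(κ(cos(heading − (PFD + offset)) − 1)), realized
  by per-millisecond Bernoulli thinning with spike times on a 0.1 ms
  sub-grid (so that 0.5 ms CCG bins are meaningful). Defaults: κ ∈ [2, 8],
  peak ∈ [20, 60] Hz, baseline ∈ [0.5, 2] Hz, untuned fractions 0.46
  (region A) and 0.88 (region B), matching the reported HD-cell prevalence
  in thalamus vs cortex; ensembles default to 20 and 30 units.
* **Reference dynamics**: both regions read the heading through a shared
  offset with three components — (i) relaxation toward gain × magnitude
  after cue rotations (τ = 20 s, modelling the slow continuous realignment
  seen experimentally; gain < 1 models under-rotation), (ii) diffusion,
  weak with the cue on (1.5°/√s) and stronger in darkness (3.5°/√s, which
  puts 2-min drift magnitudes in the ~25° range reported for darkness),
  and (iii) a fast coherent wobble (OU, SD 10°, τ = 0.5 s) representing
  the moment-to-moment fluctuation of the internal HD network that both
  regions inherit from a common attractor. The wobble is what gives paired
  decoded errors their sharp zero-lag cross-correlation; without it the
  shared signal is a slow trend whose correlation peak is a broad plateau
  and the peak lag is dominated by decoder noise. Each region adds small
  independent jitter (OU, SD 1.5°, τ = 5 s); `independent = TRUE` replaces
  the shared realization with per-region ones, and `lag_ms` delays one
  region's trace to create a ground-truth inter-regional lag.
* **Connectivity**: per presynaptic spike, a Bernoulli(p) postsynaptic
  spike at 1–5 ms latency plus Gaussian jitter.
* **Waveforms**: Gaussian trough/AHP templates with trough-to-AHP 0.55–0.85
  ms (RS) or 0.18–0.32 ms (FS).

What the generator does **not** emulate: 2-D position and egocentric cue
bearing, behavioural state changes (sleep/immobility), bursting and
refractory structure, common-input correlations beyond the shared
reference, electrode drift, and spike-sorting errors. Passing tests
therefore demonstrate that the pipeline recovers the targeted structure
when it is present and stays quiet when it is absent — not that real
recordings contain that structure, nor robustness to the artifacts above.

## Numerical choices and test scales

Ridge systems are solved in closed form; `(XᵀX + λI)` is well conditioned
after z-scoring. Zero-phase filtering is implemented in compiled code as
the exact zero-padded forward–backward recursion and is verified against
`signal::filtfilt` to the last bit. Cross-correlations over all lags use an
FFT for the lagged cross-products with cumulative sums for the per-lag
means and variances, and are verified against a direct per-lag Pearson
oracle. Degenerate inputs fail loudly: empty masks, all-zero curves,
constant circular samples, too-short windows and segments all raise.

The test suite exercises the operating characteristics at deliberately
modest scales chosen to estimate each rate with adequate precision: 200
units per class for classification (two 5-min segments, 500 shuffles), 20
seeds for the decoder benchmark (20 units, 5-min train / 2-min test, 100
shuffle decoders), 50 trials for the zero-lag property, two 26-min paired
sessions per condition for drift, 20 injected-transmission seeds and 1000
independent pairs for connectivity. These sizes are the package's own
validation design; the functions themselves accept arbitrary session
lengths and ensemble sizes.

## Known limitations

* The shuffle gate admits ~10% of uninformative sessions by construction
  (see above); treat it as a screen, not a significance test.
* The circular-correlation estimator is Fisher–Lee; values are not directly
  comparable to other circular correlation definitions.
* Concentration from smoothed curves is biased downward for very sharp
  tuning (smoothing widens the curve); classification is unaffected because
  shuffles share the bias, but absolute κ values should be read with this
  in mind.
* The detector targets excitatory connections at 1–5 ms only; inhibitory
  troughs and slower interactions are out of scope.
* With heavily drifting references, tuning curves computed over long
  windows smear; use the 2-min evaluation utilities for drift-prone
  segments.
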