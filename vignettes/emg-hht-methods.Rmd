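---
title: "Methods: EEMD and Hilbert spectral analysis of gait surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEMD and Hilbert spectral analysis of gait surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the defaults and why they were chosen, and
what the synthetic-data tests do and do not demonstrate about real
recordings.

## The analysis problem

Surface EMG recorded during the stance phase of running is short (a few
hundred milliseconds at 1000 Hz), non-stationary, and both amplitude- and
frequency-modulated: muscles fire in bursts whose timing and spectral
content shift with the foot-strike pattern. Fourier methods assume
stationarity within the analysis window; short-time methods trade time
against frequency resolution by a fixed window choice. The Hilbert–Huang
approach sidesteps both by first decomposing the signal adaptively into
intrinsic mode functions (IMFs) and then assigning each sample an
*instantaneous* amplitude and frequency via the analytic signal. The
package applies this to six lower-limb muscles (VM, VL, RF, TA, GM, GL)
across forefoot, midfoot and rearfoot strike conditions, and summarizes
each trial into features a repeated-measures design can test.

## Preprocessing

* **Band-pass 10–450 Hz, 4th order, zero phase.** The conventional surface
  EMG band. Zero phase is realized as forward–backward Butterworth
  filtering; because R's `signal::filtfilt` does not initialize the filter
  at steady state, the trace is odd-reflection padded with a pad of
  `6 × fs / low_cutoff` samples so edge transients and DC leakage decay
  outside the retained samples (interior DC rejection is below 1e-6 of the
  input level, verified in the tests).
* **Moving RMS, 50 ms, centered.** Full-wave rectification is absorbed by
  the squaring. A centered (rather than trailing) window avoids a
  systematic ~25 ms timing bias in any feature compared against burst
  timing; the effective window is the odd length `2·⌊w/2⌋+1` samples, with
  shrinking windows at the edges.
* **Stance detection.** Onset/offset are the first/last samples at or above
  20 N — a common force-platform convention — within the longest
  above-threshold run, which makes the detector robust to brief artifact
  blips. A 100 ms pre-contact window is attached for the pre-activation
  features; if it would start before the trace, the segment is flagged and
  a warning raised rather than failing the trial.
* **Amplitude normalization.** Each muscle's envelope is divided by that
  subject's mean stance-phase *peak* RMS over the three rearfoot-strike
  trials. The reference is computed from the smoothed envelope (not the raw
  rectified signal) and per muscle; both choices are the natural reading of
  peak-RMS referencing and make the features dimensionless percentages.
  Scale invariance — multiplying a subject's raw EMG by any k > 0 leaves
  normalized features unchanged — is a tested property.
* **Time normalization** interpolates stance onto a 101-point (1%) grid,
  the conventional gait-cycle resolution.

## EMD and EEMD

One sifting pass identifies strict local extrema (plateaus contribute their
floored midpoint once), fits natural cubic splines through the maxima and
minima, and subtracts the mean envelope. The two extrema nearest each end
are mirror-reflected about the first/last sample before fitting — the
standard mitigation of spline end-swings. Each IMF uses a **fixed count of
10 sifting passes** (no SD/Cauchy stopping criterion); extraction stops
when the residual is monotone or retains at most one extremum, or at the
dyadic bound `⌊log2 n⌋ − 1` IMFs. The decomposition is complete by
construction: IMFs plus residual telescope back to the input to floating
round-off (asserted at 1e-9 of the signal range on random fixtures).

Fixed-count sifting does not guarantee the textbook "extrema and
zero-crossing counts differ by at most one"; on resolvable tone mixtures
the suite checks a documented tolerance of two, and only for IMFs carrying
non-negligible energy (below 5% of the signal's sd an "IMF" is numerical
residue, not a mode). Tones closer than about a factor of two in frequency
are not separable by EMD at all — a known resolution limit, not an
implementation artifact — so the IMF-character property is asserted on
mixtures EMD can resolve.

EEMD decomposes `NE` noise-perturbed copies of the signal (white noise, sd
`Nstd × sd(signal)`, defaults `Nstd = 0.2`, `NE = 100`) and averages IMFs
index-wise. Three choices were genuinely open:

* **Per-member noise streams** are seeded from (seed, member index), so
  enlarging the ensemble never reshuffles earlier members (tested).
* **Unequal IMF counts** across members are reconciled by zero-padding at
  the slow end, preserving the fast-IMF indexing the band analysis relies
  on.
* **The returned residual** is defined as `signal − Σ averaged IMFs`, which
  restores exact completeness for the averaged set (member-wise averaging
  alone only cancels noise at the `1/√NE` rate; the tests check that rate
  separately).

With `Nstd = 0` the routine collapses to plain EMD, which is permitted and
exercised in the tests.

## Hilbert spectra and features

The analytic signal is built by the standard frequency-domain construction
(positive frequencies doubled, negative zeroed). Instantaneous frequency is
the centered finite difference of the unwrapped phase (one-sided at the
edges) — the simplest estimator consistent with `dθ/dt` — and is set to 0
where the amplitude is below 1e-10 of its maximum, where phase is
meaningless. Samples with instantaneous frequency outside `(0, 500]` Hz are
excluded from the spectrum: negative or extreme values are recognized
Hilbert-transform artifacts near edges and low-amplitude regions. Energy is
deposited as `a²(t)` (power, matching the band-power semantics) into 1 Hz
bins; the bookkeeping identity "matrix total = in-range analytic energy" is
exact and tested.

`S_max`/`F_max` are the stance-restricted argmax of the spectrum after a
small 5 Hz × 10 ms moving-average smoothing, with ties broken toward the
earliest time then lowest frequency. The kernel exists to keep a single
noisy sample from dictating the timing feature on spread EMG spectra; on
*discrete* spectra (pure tones occupying whole bins) box smoothing only
manufactures ties, so the tone-recovery tests turn it down to 1 Hz. Both
the kernel and the tie rule are configurable arguments.

Band powers sum the spectrum over `(0, 60]` and `(60, 200]` Hz in three
windows — the 100 ms before contact (absolute, not % of stance), 0–20% and
20–40% of stance — computed from the Hilbert spectrum restricted to the
window (an equivalent marginal-spectrum route exists via
`marginal_spectrum()` on a windowed spectrum). They are reported as
percentages of the per-(subject, muscle, window, band) maximum across
conditions and trials. The co-activation index uses the window-*mean*
normalized RMS of TA and GM (the defining ratio names no summary
statistic; the mean is the stable choice and the code accepts any
summaries the caller computes).

## Statistics

Trials are averaged within subject × condition before testing — the
standard treatment of a three-trial repeated design. The one-way
repeated-measures ANOVA is fitted with `stats::aov` and an
`Error(subject)` stratum; sphericity is assumed and no correction is
applied (the design has only three levels; a correction switch would be a
natural extension). Degenerate inputs are given explicit conventions: a
zero condition effect reports F = 0, p = 1; a zero error term with a
nonzero effect reports p = 0 with a `degenerate` flag. LSD post hoc
comparisons use the pooled `MS_error` on the ANOVA's error degrees of
freedom with no multiplicity adjustment — that is what "least significant
difference" means — and are cross-checked in the tests against an
independent `emmeans` computation and a brute-force sums-of-squares oracle.

## The synthetic cohort generator

No public recording accompanies the analysis design, so the generator is a
first-class, tested module that emulates the *structure* of such data: 16
subjects × 3 conditions × 3 trials at 1000 Hz, a 250 ms stance with a
150 ms lead-in and 50 ms tail, a half-sine vertical GRF (~1500 N) with a
condition-dependent early impact transient (largest for rearfoot strike),
and six EMG channels built as Gaussian burst envelopes in stance time
modulating band-limited noise carriers (15–60 Hz and 80–200 Hz, filtered
with the same Butterworth design as the preprocessing — no second filter
machinery). Injected condition effects encode the qualitative pattern
differences of interest: the medial gastrocnemius burst centered at 30% of
stance under RFS versus 45% under FFS/MFS (the headline timing effect,
~15 points of stance), earlier VM/VL/GL bursts under RFS, stronger TA
pre-activation under RFS, stronger gastrocnemius pre-activation under FFS,
and a low-band-dominant GM under MFS/RFS versus high-band-dominant under
FFS.

Between-subject variance is multiplicative log-normal on the gains
(sdlog 0.2) plus a small per-subject timing shift (sd 2% of stance) and
per-trial jitter (sd 1%); measurement noise is white with sd 0.02 relative
to burst amplitudes near 1. No study reports variance components for these
quantities, so they are free parameters chosen once at values a gait
laboratory would call realistic (roughly 20% between-subject amplitude
spread, a few-percent timing repeatability) and not revisited.

**What the tests do and do not show.** Passing the parameter-recovery and
property tests demonstrates that the pipeline recovers timing, band and
co-activation structure *of the kind injected*, at realistic noise levels,
and that every bookkeeping identity holds. The generator does not simulate
motor-unit physiology, electrode placement, movement artifact, ECG
contamination or kinematic covariates; conclusions about real recordings
still require real recordings. Notch filtering and artifact removal are
deliberately out of scope.

## Numerical and runtime choices

* The sifting loop is compiled (Rcpp): an EEMD cohort pass multiplies a
  ~1 ms EMD over 100 members × 6 muscles × 144 trials, which pure-R spline
  code would not sustain.
* The recovery experiment in the test-suite uses the full 16-subject
  cohort, 20 replicates, with the ensemble reduced to NE = 25 for the
  per-trial decompositions (the timing feature converges well before
  NE = 100; the default config keeps 100). The acceptance script reports
  the same experiment at 10 replicates.
* Determinism: every stochastic step (GRF jitter, carriers, subject
  multipliers, EEMD noise) draws from seeds derived deterministically from
  one master seed via a fixed integer chain; identical (design, seed) give
  bit-identical cohorts, feature tables and output files. Internal seeded
  draws save and restore the caller's RNG state.

## Known limitations

* Plain EMD end effects: mirror extension tames but does not eliminate
  envelope end-swings; interior-sample assertions in the tests reflect
  that.
* EMD cannot separate tones closer than ~2× in frequency; mode mixing is
  reduced (not removed) by EEMD.
* The LSD procedure controls no family-wise error by design; with three
  conditions the inflation is modest, but users wanting protection should
  adjust downstream.
* The co-activation index is undefined when both muscles are silent in a
  window; the pipeline raises a typed error for that trial rather than
  imputing.
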