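# emghht

Hilbert–Huang time–frequency analysis of lower-limb surface EMG during the
stance phase of running.

## What it is for

How runners strike the ground — forefoot (FFS), midfoot (MFS) or rearfoot
(RFS) — changes when and at which frequencies their leg muscles are
activated. Surface EMG during stance is short, non-stationary and
amplitude/frequency modulated, so classical Fourier or fixed-window
spectrograms blur exactly the timing information of interest. This package
implements the ensemble empirical mode decomposition (EEMD) / Hilbert
spectral approach to that problem, as a tested, reusable pipeline for
biomechanists and neurophysiologists:

* **Preprocessing** — zero-phase 4th-order Butterworth band-pass (10–450 Hz),
  full-wave rectification with a 50 ms moving-RMS envelope, stance detection
  from the vertical ground reaction force (20 N threshold), time
  normalization to 0–100% stance, and amplitude normalization to each
  subject's mean rearfoot-strike peak RMS.
* **Decomposition** — EMD by cubic-spline envelope sifting (fixed 10
  iterations per intrinsic mode function), and EEMD: the signal plus white
  noise of sd `0.2 × sd(signal)` is decomposed `NE = 100` times and IMFs are
  averaged index-wise. The sifting core is compiled (Rcpp).
* **Hilbert spectra** — analytic signals per IMF, instantaneous
  amplitude/frequency, the energy distribution `H(f, t)`, its marginal
  spectrum `h(f)`, the stance-phase timing `S_max` (% of stance) and
  frequency `F_max` (Hz) of maximum energy, and band powers below 60 Hz vs
  61–200 Hz in three windows (100 ms pre-contact, 0–20% and 20–40% of
  stance).
* **Co-activation** — the ankle dorsiflexor/plantarflexor index
  `CI = 2·EMG_TA / (EMG_GM + EMG_TA) × 100` (100% = balanced, >100% =
  antagonist-dominant).
* **Statistics** — one-way repeated-measures ANOVA across the three strike
  conditions with unadjusted LSD post hoc pairwise comparisons, with
  broom-style `tidy()`/`glance()` methods.
* **Synthetic gait generator** — seeded, statistically structured EMG + GRF
  cohorts (6 muscles: VM, VL, RF, TA, GM, GL) with pattern-dependent burst
  timing, band content, pre-activation and per-subject variability, so every
  stage is testable end to end without any data download.

All user-facing functions take/return tibbles or light S3 objects and chain
with the pipe; results plot with `autoplot()`.

## Worked example

Simulate a small cohort, extract features, and test the gastrocnemius
timing effect:

```r
library(emghht)
library(dplyr)

coh <- generate_cohort(effect_design(n_subjects = 4, n_trials_per_condition = 3,
                                     seed = 42))
#> <emg_cohort> 36 trials (4 subjects x 3 conditions x 3 trials)

ft <- build_feature_table(coh, default_config(eemd = list(ne = 25), seed = 42))
ft |> select(subject:window, rms_pct, s_max_pct, f_max_hz) |> head(4)
#> # A tibble: 4 × 8
#>   subject condition trial muscle window rms_pct s_max_pct f_max_hz
#>     <int> <chr>     <int> <chr>  <chr>    <dbl>     <dbl>    <dbl>
#> 1       1 FFS           1 VM     pre       8.46      49.0    128.
#> 2       1 FFS           1 VL     pre       9.93      40.1    138.
#> 3       1 FFS           1 RF     pre       9.28      51.0     79.5
#> 4       1 FFS           1 TA     pre      17.3       16.6    174.

gm <- ft |> filter(muscle == "GM", window == "early") |>
  transmute(subject, condition, value = s_max_pct)
fit <- rm_anova(gm)
fit
#> One-way repeated-measures ANOVA: F(2, 6) = 16.79, p = 0.003482
#> condition means: FFS = 46.52, MFS = 44.64, RFS = 29.96

lsd_pairwise(fit) |> select(pair, mean_diff, statistic, p.value)
#> # A tibble: 3 × 4
#>   pair      mean_diff statistic p.value
#>   <chr>         <dbl>     <dbl>   <dbl>
#> 1 FFS - MFS      1.89     0.604 0.568
#> 2 FFS - RFS     16.6      5.29  0.00184
#> 3 MFS - RFS     14.7      4.69  0.00336
```

Reading the output: each feature row is one (subject, condition, trial,
muscle, analysis window). `rms_pct` is the window-mean RMS envelope as a
percentage of that subject's rearfoot-strike peak; `s_max_pct` and
`f_max_hz` locate the Hilbert-spectrum energy maximum within stance;
`p_low`/`p_high` (not shown) are band powers as percentages of the
per-subject maximum across conditions; rows with `muscle == "TA/GM"` carry
the co-activation index `ci_pct`. Here the generator injected a medial
gastrocnemius burst at 30% of stance under RFS versus 45% under FFS/MFS;
the pipeline recovers an earlier RFS `S_max` by ~15 points of stance and
the repeated-measures ANOVA with LSD comparisons flags RFS against both
other conditions.

The full pipeline (simulate → features → statistics → CSV/JSON artifacts)
runs in one call or from the shell:

```r
run_pipeline(default_config(), out_dir = "out")
```

```sh
inst/cli/emghht simulate --out trials --seed 1
inst/cli/emghht analyze --manifest trials/manifest.csv --out out
inst/cli/emghht stats --features out/features.csv --out out
```

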