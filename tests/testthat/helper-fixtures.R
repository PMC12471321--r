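# Shared fixture builders. Everything is generated in code, seeded.

FS <- 1000

tone <- function(freq, duration = 1, fs = FS, amp = 1, phase = 0) {
  t <- seq(0, duration, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}

two_tone <- function(f1 = 25, f2 = 150, duration = 1, fs = FS) {
  list(t = seq(0, duration, by = 1 / fs),
       c1 = tone(f1, duration, fs), c2 = tone(f2, duration, fs),
       x = tone(f1, duration, fs) + tone(f2, duration, fs))
}

linear_chirp <- function(f0 = 30, f1 = 150, duration = 1, fs = FS) {
  t <- seq(0, duration, by = 1 / fs)
  list(t = t, x = sin(2 * pi * (f0 * t + (f1 - f0) / 2 * t^2)),
       inst_freq = f0 + (f1 - f0) * t)
}

# random smooth-ish signal: a few tones + noise, seeded
random_fixture <- function(seed, n = 600, fs = FS) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  freqs <- runif(3, 10, 200)
  amps <- runif(3, 0.3, 1)
  x <- rowSums(sapply(1:3, function(i) amps[i] * sin(2 * pi * freqs[i] * t +
                                                       runif(1, 0, 2 * pi))))
  x + rnorm(n, 0, 0.2)
}

# rectangular GRF: zeros, plateau above threshold, zeros -> known stance
rect_grf <- function(n_pre = 100, n_stance = 300, n_post = 100, level = 800,
                     fs = FS) {
  signal_trace(c(numeric(n_pre), rep(level, n_stance), numeric(n_post)),
               fs, t0 = -n_pre / fs)
}

# hand-built Hilbert spectrum for argmax / tie-break tests
manual_spectrum <- function(energy, fs = FS, bin_width = 1) {
  nb <- nrow(energy)
  structure(list(energy = energy,
                 freq_edges = seq(0, nb * bin_width, by = bin_width),
                 freq_centers = (seq_len(nb) - 0.5) * bin_width,
                 freq_bin_width = bin_width, fmax = nb * bin_width,
                 fs = fs, t0 = 0, in_range_energy = sum(energy)),
            class = "hilbert_spectrum")
}

burst_params <- function(burst_center = 0.5, burst_width = 0.15,
                         low_band_gain = 1, high_band_gain = 1,
                         pre_activation_gain = 0) {
  list(burst_center = burst_center, burst_width = burst_width,
       low_band_gain = low_band_gain, high_band_gain = high_band_gain,
       pre_activation_gain = pre_activation_gain)
}

small_cohort_design <- function(n_subjects = 2, n_trials = 1, seed = 11, ...) {
  effect_design(n_subjects = n_subjects, n_trials_per_condition = n_trials,
                seed = seed, ...)
}

fast_config <- function(ne = 10, muscles = c("TA", "GM"), seed = 7) {
  default_config(eemd = list(ne = ne), muscles = muscles, seed = seed)
}
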