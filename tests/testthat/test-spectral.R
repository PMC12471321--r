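test_that("analytic signal recovers amplitude and frequency of a pure tone", {
  t <- seq(0, 1, by = 1 / FS)
  a <- analytic_signal(cos(2 * pi * 50 * t), FS)
  interior <- 100:900
  expect_lt(max(abs(a$amplitude[interior] - 1)), 0.01)
  expect_lt(max(abs(a$inst_freq[interior] - 50)), 0.5)
})

test_that("analytic signal tracks an amplitude modulator", {
  t <- seq(0, 1, by = 1 / FS)
  mod <- 1 + 0.5 * sin(2 * pi * 2 * t)
  a <- analytic_signal(mod * cos(2 * pi * 100 * t), FS)
  interior <- 100:900
  expect_lt(max(abs(a$amplitude[interior] - mod[interior]) / mod[interior]), 0.03)
})

test_that("analytic signal of silence is zero amplitude and zero frequency", {
  a <- analytic_signal(numeric(64), FS)
  expect_equal(a$amplitude, numeric(64))
  expect_equal(a$inst_freq, numeric(64))
  expect_true(all(is.finite(a$phase)))
})

test_that("the Hilbert spectrum concentrates a tone and conserves energy", {
  x <- tone(50)
  dec <- emd_decompose(signal_trace(x, FS))
  hs <- hilbert_spectrum(dec)
  # >= 95% of deposited energy within 49-51 Hz
  rows <- which(hs$freq_centers >= 49 & hs$freq_centers <= 51)
  expect_gte(sum(hs$energy[rows, ]) / sum(hs$energy), 0.95)

  # bookkeeping identity, recomputed independently from the IMFs
  total <- 0
  for (k in seq_len(ncol(dec$imfs))) {
    a <- analytic_signal(dec$imfs[, k], FS)
    keep <- a$inst_freq > 0 & a$inst_freq <= 500
    total <- total + sum(a$amplitude[keep]^2)
  }
  expect_equal(sum(hs$energy), total, tolerance = 1e-12)
  expect_equal(hs$in_range_energy, total, tolerance = 1e-12)
})

test_that("an empty IMF set gives an all-zero spectrum", {
  ramp <- emd_decompose(signal_trace(seq(0, 1, length.out = 200), FS))
  expect_equal(ncol(ramp$imfs), 0)
  hs <- hilbert_spectrum(ramp)
  expect_true(all(hs$energy == 0))
  expect_equal(marginal_spectrum(hs)$energy, rep(0, nrow(hs$energy)))
})

test_that("the marginal spectrum peaks at the mixture tones and sums exactly", {
  tt <- two_tone()
  hs <- hilbert_spectrum(emd_decompose(signal_trace(tt$x, FS)))
  h <- marginal_spectrum(hs)
  expect_equal(sum(h$energy), sum(hs$energy), tolerance = 1e-12)

  # dominant peaks, after light smoothing against beat-splitting, within
  # 2 bins of each tone
  sm <- stats::filter(h$energy, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  lo_peak <- h$freq_hz[which.max(sm * (h$freq_hz < 90))]
  hi_peak <- h$freq_hz[which.max(sm * (h$freq_hz >= 90))]
  expect_lte(abs(lo_peak - 25), 2)
  expect_lte(abs(hi_peak - 150), 2)
})

test_that("maximum-energy location finds a burst and honors tie-breaks", {
  # 120 Hz tone under a Gaussian envelope centered at 30% of a 300-sample
  # stance, quiet elsewhere
  n <- 500
  seg <- detect_stance(rect_grf(100, 300, 100))
  center <- seg$onset_index + 0.30 * (seg$offset_index - seg$onset_index)
  env <- exp(-0.5 * ((seq_len(n) - center) / 25)^2)
  x <- env * tone(120, (n - 1) / FS)
  hs <- hilbert_spectrum(emd_decompose(signal_trace(x, FS)))
  mx <- locate_max_energy(hs, seg)
  expect_lte(abs(mx$s_max_pct - 30), 2)
  expect_lte(abs(mx$f_max_hz - 120), 5)

  # uniform energy: earliest time, lowest frequency bin
  seg2 <- detect_stance(rect_grf(120, 100, 20, fs = FS))
  hs_u <- manual_spectrum(matrix(1, 200, 240))
  mx_u <- locate_max_energy(hs_u, seg2)
  expect_equal(mx_u$s_max_pct, 0)
  expect_equal(mx_u$f_max_hz, 0.5)

  # two identical bursts at 20% and 60% of stance: the earlier one wins
  e <- matrix(0, 200, 240)
  span <- seg2$offset_index - seg2$onset_index
  cols <- seq_len(ncol(e))
  bump <- function(c0) 5 * exp(-0.5 * ((cols - c0) / 4)^2)
  ridge <- bump(seg2$onset_index + round(0.20 * span)) +
    bump(seg2$onset_index + round(0.60 * span))
  for (r in 78:82) e[r, ] <- ridge
  mx_2 <- locate_max_energy(manual_spectrum(e), seg2)
  expect_equal(mx_2$s_max_pct, 100 * round(0.20 * span) / span)

  expect_error(locate_max_energy(manual_spectrum(matrix(0, 10, 240)), seg2),
               class = "emghht_undefined_features")
})

test_that("band power splits a tone correctly and respects the partition bound", {
  x <- tone(30)
  hs <- hilbert_spectrum(emd_decompose(signal_trace(x, FS)))
  w <- c(101, 901)
  p_low <- band_power(hs, c(0, 60), w)
  p_high <- band_power(hs, c(60, 200), w)
  total <- sum(hs$energy[, 101:900])
  expect_gte(p_low, 0.95 * total)
  expect_lte(p_high, 0.05 * total)
  expect_lte(p_low + p_high, total + 1e-12)

  expect_equal(band_power(hs, c(0, 60), c(1, 2)) +
                 band_power(hs, c(60, 500), c(1, 2)),
               sum(hs$energy[, 1]), tolerance = 1e-12)

  # zero-energy window
  zero_hs <- manual_spectrum(matrix(0, 50, 30))
  expect_equal(band_power(zero_hs, c(0, 60), c(1, 10)), 0)
  expect_error(band_power(hs, c(0, 60), c(10, 10)),
               class = "emghht_invalid_argument")
})

test_that("band-power normalization is a within-group max percentage", {
  df <- tidyr::crossing(subject = 1, muscle = "GM", window = "early",
                        band = "p_low", condition = c("FFS", "MFS", "RFS"))
  df$power <- c(2, 4, 8)
  out <- normalize_band_power(df)
  expect_equal(sort(out$power_pct), c(25, 50, 100))

  single <- df[1, ]
  expect_equal(normalize_band_power(single)$power_pct, 100)

  # scale invariance
  df2 <- df; df2$power <- df$power * 17
  expect_equal(normalize_band_power(df2)$power_pct, out$power_pct)

  dfz <- df; dfz$power <- 0
  expect_warning(outz <- normalize_band_power(dfz),
                 class = "emghht_zero_power_group")
  expect_equal(outz$power_pct, c(0, 0, 0))
})

test_that("tone frequency is recovered across the EMG band", {
  # the argmax-stabilizing kernel exists for noisy spread spectra; a pure
  # tone deposits whole bins, where box smoothing only creates ties, so the
  # kernel is turned down to its 1 Hz setting here
  for (f in c(20, 80, 200)) {
    x <- tone(f)
    dec <- emd_decompose(signal_trace(x, FS))
    hs <- hilbert_spectrum(dec)
    seg <- detect_stance(rect_grf(100, 800, 101))
    mx <- locate_max_energy(hs, seg, smooth_hz = 1)
    expect_lte(abs(mx$f_max_hz - f), max(2, 0.03 * f))
  }
})
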