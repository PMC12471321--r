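test_that("extrema detection counts cycles, ignores monotone input, handles plateaus", {
  x <- tone(3, duration = 1)  # 3 full cycles
  ex <- find_extrema(x)
  expect_equal(length(ex$maxima), 3)
  expect_equal(length(ex$minima), 3)

  ex <- find_extrema(seq(0, 1, length.out = 50))
  expect_equal(length(ex$maxima), 0)
  expect_equal(length(ex$minima), 0)

  # plateau midpoint, floored: [0, 1, 1, 0] peaks once at the 2nd sample
  ex <- find_extrema(c(0, 1, 1, 0))
  expect_equal(ex$maxima, 2L)
  expect_equal(length(ex$minima), 0)
  # longer plateau: [0, 1, 1, 1, 0] -> midpoint sample 3
  expect_equal(find_extrema(c(0, 1, 1, 1, 0))$maxima, 3L)
})

test_that("spline envelopes bracket a sinusoid and pass through their knots", {
  x <- tone(10, duration = 1)
  ex <- find_extrema(x)
  env <- spline_envelopes(x, ex$maxima, ex$minima)
  interior <- 100:900
  expect_lt(max(abs(env$mean[interior])), 0.02)

  # adding a constant shifts the envelope mean by that constant
  env_c <- spline_envelopes(x + 3)
  expect_lt(max(abs(env_c$mean[interior] - 3)), 0.02)

  # interpolation property at the knots
  expect_equal(env$upper[ex$maxima], x[ex$maxima], tolerance = 1e-10)
  expect_equal(env$lower[ex$minima], x[ex$minima], tolerance = 1e-10)
  expect_true(all(env$upper[ex$maxima] >= x[ex$maxima] - 1e-10))

  expect_error(spline_envelopes(seq_len(20) / 2), class = "emghht_cannot_sift")
})

test_that("fixed-count sifting extracts a pure tone and respects the identity", {
  x <- tone(50, duration = 1)
  s <- sift_imf(x, 10)
  expect_true(s$completed)
  expect_gt(cor(s$imf, x), 0.999)
  expect_lt(max(abs(s$residual_after[100:900])), 0.01)
  expect_equal(s$imf + s$residual_after, x, tolerance = 1e-12)

  expect_error(sift_imf(numeric(100)), class = "emghht_cannot_sift")
})

test_that("EMD separates a two-tone mixture and telescopes back to the input", {
  tt <- two_tone()
  dec <- emd_decompose(signal_trace(tt$x, FS))
  expect_gte(ncol(dec$imfs), 2)
  expect_gt(abs(cor(dec$imfs[, 1], tt$c2)), 0.95)
  expect_gt(abs(cor(dec$imfs[, 2], tt$c1)), 0.95)

  recon <- rowSums(dec$imfs) + dec$residual
  expect_lt(max(abs(recon - tt$x)), 1e-9 * diff(range(tt$x)))

  # a monotone ramp yields no IMFs; the residual is the ramp
  ramp <- seq(0, 1, length.out = 200)
  dr <- emd_decompose(signal_trace(ramp, FS))
  expect_equal(ncol(dr$imfs), 0)
  expect_equal(dr$residual, ramp)
})

test_that("IMFs have near-balanced extrema and zero-crossing counts", {
  # fixed-count sifting keeps |#extrema - #crossings| <= 2 on mixtures EMD
  # can actually resolve (tones separated by well over a factor of two;
  # closer tones leave riding waves, a known resolution limit of EMD)
  for (seed in 1:4) {
    set.seed(seed)
    t <- (0:799) / FS
    base <- runif(1, 10, 15)
    freqs <- base * c(1, 3.5, 12) * runif(3, 0.95, 1.05)
    x <- rowSums(sapply(freqs, function(f) {
      runif(1, 0.3, 1) * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
    }))
    dec <- emd_decompose(signal_trace(x, FS))
    for (k in seq_len(max(0, ncol(dec$imfs) - 1))) {
      imf <- dec$imfs[, k]
      if (sd(imf) < 0.05 * sd(x)) next  # numerical residue, not a mode
      ex <- find_extrema(imf)
      n_ext <- length(ex$maxima) + length(ex$minima)
      n_zc <- sum(abs(diff(sign(imf))) > 0)
      expect_lte(abs(n_ext - n_zc), 2)
    }
  }
})

test_that("IMF order runs fast to slow in median instantaneous frequency", {
  for (pair in list(c(25, 150), c(40, 160))) {
    x <- tone(pair[1]) + tone(pair[2])
    dec <- emd_decompose(signal_trace(x, FS))
    med_f <- sapply(1:2, function(k) {
      median(analytic_signal(dec$imfs[, k], FS)$inst_freq[100:900])
    })
    expect_gte(med_f[1], med_f[2])
  }
})

test_that("a degenerate ensemble (NE = 1, no noise) reproduces plain EMD", {
  tt <- two_tone(duration = 0.5)
  plain <- emd_decompose(signal_trace(tt$x, FS))
  ens <- eemd_decompose(signal_trace(tt$x, FS),
                        eemd_config(nstd = 0, ne = 1, seed = 5))
  expect_equal(ens$imfs, plain$imfs)
  expect_equal(ens$residual, plain$residual)
})

test_that("EEMD is deterministic in its seed and complete by construction", {
  x <- random_fixture(9, n = 500)
  cfg <- eemd_config(ne = 20, seed = 42)
  d1 <- eemd_decompose(signal_trace(x, FS), cfg)
  d2 <- eemd_decompose(signal_trace(x, FS), cfg)
  expect_identical(d1$imfs, d2$imfs)
  expect_equal(rowSums(d1$imfs) + d1$residual, x, tolerance = 1e-12)

  # different seeds give different ensembles
  d3 <- eemd_decompose(signal_trace(x, FS), eemd_config(ne = 20, seed = 43))
  expect_false(identical(d1$imfs, d3$imfs))
})

test_that("growing the ensemble keeps earlier members' contribution stable", {
  # member-wise seeding: NE=10 and NE=20 share the first 10 noise draws,
  # so the NE=20 average moves by less than a fresh independent ensemble
  x <- random_fixture(13, n = 400)
  d10 <- eemd_decompose(signal_trace(x, FS), eemd_config(ne = 10, seed = 3))
  d20 <- eemd_decompose(signal_trace(x, FS), eemd_config(ne = 20, seed = 3))
  dfresh <- eemd_decompose(signal_trace(x, FS), eemd_config(ne = 10, seed = 999))
  k <- min(ncol(d10$imfs), ncol(d20$imfs), ncol(dfresh$imfs))
  drift <- sqrt(mean((d20$imfs[, 1:k] - d10$imfs[, 1:k])^2))
  indep <- sqrt(mean((dfresh$imfs[, 1:k] - d10$imfs[, 1:k])^2))
  expect_lt(drift, indep)
})

test_that("ensemble averaging converges like one over the square root of NE", {
  # the spread between independent ensembles of size NE scales ~ 1/sqrt(NE):
  # quadrupling NE should roughly halve the IMF1 difference between seeds
  tt <- two_tone(duration = 0.5)
  spread <- function(ne) {
    a <- eemd_decompose(signal_trace(tt$x, FS), eemd_config(ne = ne, seed = 1))
    b <- eemd_decompose(signal_trace(tt$x, FS), eemd_config(ne = ne, seed = 2))
    sqrt(mean((a$imfs[, 1] - b$imfs[, 1])^2))
  }
  r <- spread(25) / spread(100)
  expect_gt(r, 1.3)
  expect_lt(r, 3.1)
})
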