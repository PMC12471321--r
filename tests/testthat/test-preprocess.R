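test_that("band-pass filter removes DC, passes the EMG band, rejects low drift", {
  n <- 1000
  const <- signal_trace(rep(5, n), FS)
  y <- bandpass_filter(const)$samples
  expect_lt(max(abs(y[100:900])), 1e-6 * 5)

  s50 <- bandpass_filter(signal_trace(tone(50)[1:n], FS))$samples
  expect_lt(abs(max(abs(s50[101:900])) - 1), 0.02)

  s2 <- bandpass_filter(signal_trace(tone(2)[1:n], FS))$samples
  expect_lt(max(abs(s2[101:900])), 0.10)
})

test_that("band-pass filter validates its corner frequencies", {
  tr <- signal_trace(rnorm(100), FS)
  expect_error(bandpass_filter(tr, high = 500), class = "emghht_invalid_argument")
  expect_error(bandpass_filter(tr, low = 0), class = "emghht_invalid_argument")
})

test_that("moving RMS matches closed forms and an enumeration oracle", {
  n <- 500
  env <- moving_rms(signal_trace(rep(-3, n), FS), 0.051)$samples
  expect_equal(env, rep(3, n))

  # sinusoid over whole cycles: RMS = 1/sqrt(2)
  env <- moving_rms(signal_trace(tone(100)[1:n], FS), 0.050)$samples
  expect_lt(max(abs(env[100:400] - 1 / sqrt(2))), 0.01)

  # impulse against direct enumeration: the centered 51-sample window
  # containing the impulse averages 1/51 in power
  x <- numeric(201); x[101] <- 1
  w <- 51
  oracle <- sapply(seq_along(x), function(i) {
    lo <- max(1, i - w %/% 2); hi <- min(length(x), i + w %/% 2)
    sqrt(mean(x[lo:hi]^2))
  })
  env <- moving_rms(signal_trace(x, FS), w / FS)$samples
  expect_equal(env, oracle, tolerance = 1e-12)
  expect_equal(max(env), 1 / sqrt(w))

  expect_error(moving_rms(signal_trace(rnorm(10), FS), 0.050),
               class = "emghht_invalid_argument")
})

test_that("stance detection finds the generator's true onset and the longest run", {
  g <- generate_grf(0.25, FS, "FFS", seed = 2)
  seg <- detect_stance(g)
  expect_equal(seg$onset_index, attr(g, "truth")$onset_index)
  expect_lte(abs((seg$offset_index - seg$onset_index + 1) - 250), 2)

  expect_error(detect_stance(signal_trace(numeric(300), FS)),
               class = "emghht_no_stance")

  # an artifact blip before the real stance: longest run must win
  x <- numeric(600)
  x[50:60] <- 100          # 11-sample artifact
  x[200:450] <- 900        # true stance
  seg <- detect_stance(signal_trace(x, FS))
  expect_equal(seg$onset_index, 200L)
  expect_equal(seg$offset_index, 450L)
})

test_that("stance detection warns when the pre-window leaves the trace", {
  x <- c(rep(0, 30), rep(500, 200), rep(0, 50))
  expect_warning(seg <- detect_stance(signal_trace(x, FS)),
                 class = "emghht_truncated_pre_window")
  expect_true(seg$pre_window_truncated)
})

test_that("RMS normalization is linear and the RFS reference is the trial mean", {
  env <- moving_rms(signal_trace(abs(tone(80, 0.5)), FS), 0.05)
  pk <- max(env$samples)
  expect_equal(max(normalize_rms(env, pk)$samples), 1)
  expect_equal(max(normalize_rms(env, 2 * pk)$samples), 0.5)
  expect_error(normalize_rms(env, 0), class = "emghht_invalid_argument")

  peaks <- tibble::tibble(
    subject = 1, muscle = "GM",
    condition = c("RFS", "RFS", "RFS", "FFS"),
    peak = c(2, 3, 4, 99))
  expect_equal(rfs_reference(peaks)$reference, 3)
})

test_that("time normalization preserves lines, identity grids, and peak location", {
  n <- 400
  seg <- detect_stance(rect_grf(100, 300, 100))
  ramp <- signal_trace(seq(0, 1, length.out = 500), FS)
  out <- time_normalize(ramp, seg)
  expect_equal(length(out), 101)
  expect_equal(out, seq(ramp$samples[seg$onset_index],
                        ramp$samples[seg$offset_index], length.out = 101),
               tolerance = 1e-9)

  # stance of exactly 101 samples reproduces the input samples
  seg101 <- suppressWarnings(detect_stance(rect_grf(50, 101, 50)))
  x <- signal_trace(rnorm(201), FS)
  expect_equal(time_normalize(x, seg101),
               x$samples[seg101$onset_index:seg101$offset_index],
               tolerance = 1e-12)

  # peak placed at 30% of stance recovered within 1%
  span <- seg$offset_index - seg$onset_index
  y <- numeric(500)
  idx <- seg$onset_index + round(0.30 * span)
  y <- exp(-0.5 * ((seq_len(500) - idx) / 15)^2)
  tn <- time_normalize(signal_trace(y, FS), seg)
  expect_lte(abs((which.max(tn) - 1) - 30), 1)

  expect_error(time_normalize(ramp, structure(
    list(onset_index = 10L, offset_index = 10L, pre_window_samples = 5L,
         fs = FS, pre_window_truncated = FALSE), class = "stance_segment")),
    class = "emghht_invalid_argument")
})

test_that("filter + RMS envelope is shift-equivariant away from edges", {
  set.seed(3)
  x <- random_fixture(3, n = 1500)
  shift <- 100
  xs <- c(x[(shift + 1):1500], x[1:shift])  # circular shift left
  pipeline <- function(v) {
    moving_rms(bandpass_filter(signal_trace(v, FS)), 0.05)$samples
  }
  y <- pipeline(x)
  ys <- pipeline(xs)
  interior <- 400:1000
  expect_lt(max(abs(ys[interior] - y[interior + shift])), 1e-3 * max(abs(y)))
})

test_that("amplitude normalization cancels any per-subject scale factor", {
  set.seed(4)
  x <- random_fixture(4, n = 800)
  seg <- detect_stance(rect_grf(100, 500, 200))
  env <- function(v) {
    moving_rms(bandpass_filter(signal_trace(v, FS)), 0.05)
  }
  for (k in c(0.2, 5)) {
    e1 <- env(x); ek <- env(k * x)
    r1 <- max(e1$samples[seg$onset_index:seg$offset_index])
    rk <- max(ek$samples[seg$onset_index:seg$offset_index])
    expect_equal(normalize_rms(ek, rk)$samples, normalize_rms(e1, r1)$samples,
                 tolerance = 1e-9)
  }
})
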