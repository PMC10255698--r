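test_that("bandpass filter preserves length, fs, and maps zero to zero", {
  x <- raw_ecg(numeric(1000), 250)
  y <- bandpass_filter(x)
  expect_equal(length(y$samples), 1000L)
  expect_equal(y$fs, 250)
  expect_equal(y$samples, numeric(1000))
})

test_that("bandpass passes 10 Hz, removes DC offset and 0.05 Hz drift", {
  t <- (0:2499) / 250
  ctr <- 251:2250  # central 8 s, away from edge transients
  x <- raw_ecg(sin(2 * pi * 10 * t) + 5, 250)
  y <- bandpass_filter(x)
  pure_rms <- rms(sin(2 * pi * 10 * t[ctr]))
  expect_lt(abs(rms(y$samples[ctr]) - pure_rms) / pure_rms, 0.10)
  expect_lt(abs(mean(y$samples[ctr])), 0.05)

  drift <- raw_ecg(sin(2 * pi * 0.05 * t), 250)
  yd <- bandpass_filter(drift)
  atten_db <- 20 * log10(rms(yd$samples[ctr]) / rms(drift$samples[ctr]))
  expect_lte(atten_db, -20)
})

test_that("bandpass validates its band against Nyquist and is linear", {
  x <- raw_ecg(rnorm(500), 250)
  expect_error(bandpass_filter(x, 0.5, 130), "Nyquist")
  expect_error(bandpass_filter(x, 10, 5), "low_hz < high_hz")
  y1 <- bandpass_filter(x)$samples
  x3 <- raw_ecg(3 * x$samples, 250)
  expect_equal(bandpass_filter(x3)$samples, 3 * y1, tolerance = 1e-8)
})

test_that("resampling obeys the exact length contract", {
  x <- raw_ecg(rnorm(2500), 250)
  y <- resample_signal(x, 125)
  expect_equal(length(y$samples), 1250L)
  expect_equal(y$fs, 125)
  # identity resampling
  same <- resample_signal(x, 250)
  expect_equal(same$samples, x$samples, tolerance = 1e-9)
  # non-integer ratio still lands on round(n * ratio)
  odd <- resample_signal(raw_ecg(rnorm(1000), 360), 125)
  expect_equal(length(odd$samples), round(1000 * 125 / 360))
})

test_that("resampling keeps the dominant frequency in place", {
  t <- (0:2499) / 250
  x <- raw_ecg(sin(2 * pi * 5 * t), 250)
  y <- resample_signal(x, 125)
  n <- length(y$samples)
  sp <- abs(stats::fft(y$samples))[1:(n %/% 2)]
  peak_hz <- (which.max(sp) - 1) * 125 / n
  expect_equal(peak_hz, 5, tolerance = 0.1)
})

test_that("normalize_beat gives mean 0 / population sd 1 and is idempotent", {
  expect_equal(normalize_beat(c(1, 2, 3)), c(-1.2247, 0, 1.2247),
               tolerance = 1e-3)
  x <- rnorm(200, mean = 3, sd = 7)
  z <- normalize_beat(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  expect_equal(normalize_beat(z), z, tolerance = 1e-9)
  expect_warning(out <- normalize_beat(c(4, 4, 4, 4)), "constant")
  expect_equal(out, numeric(4))
})

test_that("segment_beats finds each beat of a clean periodic trace", {
  m <- beat_morphology(
    0L,
    wave_centers = c(P = 0.28, Q = 0.44, R = 0.50, S = 0.56, T = 0.72),
    wave_amplitudes = c(P = 0.15, Q = -0.12, R = 1, S = -0.25, T = 0.30),
    wave_widths = c(P = 0.035, Q = 0.012, R = 0.018, S = 0.014, T = 0.06),
    jitter_sd = 0, noise_sd = 0, wander_amp = 0
  )
  one <- generate_beat(m, 125, seed = 0)$samples  # one beat per second at 125 Hz
  trace <- raw_ecg(rep(one, 8), 125)
  segs <- segment_beats(trace, length = 186)
  expect_length(segs, 8L)
  for (s in segs) {
    expect_length(s$samples, 186L)
    expect_lt(abs(mean(s$samples)), 1e-9)
  }
})

test_that("segment_beats handles flat and too-short traces gracefully", {
  expect_length(segment_beats(raw_ecg(numeric(1000), 125)), 0L)
  expect_warning(out <- segment_beats(raw_ecg(rnorm(100), 125), length = 186),
                 "shorter")
  expect_length(out, 0L)
})

test_that("the chain preserves duration bookkeeping", {
  x <- raw_ecg(rnorm(2500), 250)
  f <- bandpass_filter(x)
  expect_equal(f$duration_s, x$duration_s)
  r <- resample_signal(f, 125)
  expect_equal(r$duration_s, x$duration_s)
})
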