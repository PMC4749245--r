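test_that("episode extraction returns the pre-shock window with the right sample count", {
  fs <- 250
  rec <- sin(2 * pi * 7 * (0:(120 * fs - 1)) / fs)  # 120 s recording
  ep <- extract_episode(rec, fs, shock_time = 100)
  expect_s3_class(ep, "ecg_episode")
  expect_length(ep$samples, 512L)  # round(2.05 * 250)
  # window is [97.45, 99.5): first sample is the one at t = 97.45 s
  i0 <- round(97.45 * fs) + 1L
  expect_identical(ep$samples, rec[i0:(i0 + 511L)])
  rec500 <- sin(2 * pi * 7 * (0:(60 * 500 - 1)) / 500)
  expect_length(extract_episode(rec500, 500, shock_time = 50)$samples, 1025L)
})

test_that("episode extraction refuses windows outside the recording", {
  rec <- rnorm(500)
  expect_error(extract_episode(rec, 250, shock_time = 1), "episode unavailable")
  expect_error(extract_episode(rec, 250, shock_time = 1e4), "episode unavailable")
})

test_that("band-pass keeps mid-band energy, kills DC and out-of-band energy", {
  fs <- 250
  n <- 512
  t <- (0:(n - 1)) / fs
  bin <- function(k) k * fs / n
  mid <- ecg_episode(sin(2 * pi * bin(20) * t), fs)           # ~9.8 Hz
  out_mid <- bandpass_filter(mid)
  expect_gt(max(abs(out_mid$samples)) / max(abs(mid$samples)),
            10^(-1 / 20))                                     # <= 1 dB loss
  dc <- ecg_episode(rep(1, n), fs)
  expect_lt(max(abs(bandpass_filter(dc)$samples)), 0.01)
  zero <- ecg_episode(rep(0, n), fs)
  expect_equal(bandpass_filter(zero)$samples, rep(0, n))
  # designed response: >= 20 dB down at half the low edge and twice the
  # high edge, <= 1 dB ripple mid-band
  g <- bandpass_gain(c(1, 10, 96), 2, 48, fs)
  expect_lt(g[1], 10^(-20 / 20))
  expect_gt(g[2], 10^(-1 / 20))
  expect_lt(g[3], 10^(-20 / 20))
  expect_error(bandpass_filter(mid, low = 50, high = 40), "band edges")
})

test_that("amplitude spectrum recovers bin-aligned sinusoid amplitudes", {
  fs <- 250
  n <- 512
  t <- (0:(n - 1)) / fs
  f1 <- 20 * fs / n
  f2 <- 51 * fs / n
  x <- 1.0 * sin(2 * pi * f1 * t) + 0.4 * cos(2 * pi * f2 * t)
  sp <- amplitude_spectrum(ecg_episode(x, fs))
  expect_equal(sp$resolution, fs / n)
  expect_equal(sp$amplitudes[sp$frequencies == f1], 1.0, tolerance = 1e-8)
  expect_equal(sp$amplitudes[sp$frequencies == f2], 0.4, tolerance = 1e-8)
  expect_lt(max(sp$amplitudes[!sp$frequencies %in% c(f1, f2)]), 1e-10)
  expect_equal(amplitude_spectrum(ecg_episode(rep(0, n), fs))$amplitudes,
               rep(0, floor(n / 2) + 1L))
})

test_that("AMSA of a single bin-aligned sinusoid is amplitude x frequency", {
  fs <- 250
  n <- 512
  t <- (0:(n - 1)) / fs
  f20 <- 20 * fs / n  # ~9.756 Hz
  sp <- amplitude_spectrum(ecg_episode(0.5 * sin(2 * pi * f20 * t), fs))
  expect_equal(compute_amsa(sp), 0.5 * f20, tolerance = 0.01)
  expect_equal(compute_amsa(amplitude_spectrum(ecg_episode(rep(0, n), fs))), 0)
  expect_error(compute_amsa(sp, band_low = 49, band_high = 48), "band_low")
  expect_error(compute_amsa(sp, band_low = 48.4, band_high = 48.6),
               "no spectral bins")
})

test_that("AMSA is homogeneous and monotone in the band on random signals", {
  fs <- 250
  n <- 512
  withr::with_seed(42, {
    for (rep in 1:20) {
      x <- rnorm(n)
      ep <- ecg_episode(x, fs)
      sp <- amplitude_spectrum(ep)
      c_scale <- runif(1, 0.5, 3)
      sp_scaled <- amplitude_spectrum(ecg_episode(c_scale * x, fs))
      expect_equal(compute_amsa(sp_scaled), c_scale * compute_amsa(sp),
                   tolerance = 1e-12)
      lo <- runif(1, 2, 20)
      hi <- runif(1, 25, 48)
      expect_lte(compute_amsa(sp, lo, hi),
                 compute_amsa(sp, lo - 1, hi + 1) + 1e-12)
    }
  })
})

test_that("FFT spectrum path agrees with the naive DFT oracle", {
  fs <- 250
  withr::with_seed(7, {
    for (n in c(128L, 250L, 512L)) {
      x <- rnorm(n)
      sp <- amplitude_spectrum(ecg_episode(x, fs))
      oracle <- amplitude_spectrum_naive(x, fs)
      expect_equal(sp$amplitudes, oracle$amplitudes, tolerance = 1e-9)
      expect_equal(compute_amsa(sp),
                   sum(oracle$amplitudes[oracle$frequencies >= 2 &
                                           oracle$frequencies <= 48] *
                         oracle$frequencies[oracle$frequencies >= 2 &
                                              oracle$frequencies <= 48]),
                   tolerance = 1e-9)
    }
  })
})

test_that("single-sided spectral power matches time-domain power (Parseval)", {
  fs <- 250
  withr::with_seed(11, {
    for (rep in 1:5) {
      x <- rnorm(512)
      sp <- amplitude_spectrum(ecg_episode(x, fs))
      # interior bins carry amplitude 2|X|/N -> power A^2/2; DC and
      # Nyquist carry A^2
      n <- 512L
      k <- seq_along(sp$amplitudes) - 1L
      edge <- k == 0L | k == n / 2L
      p_spec <- sum(ifelse(edge, sp$amplitudes^2, sp$amplitudes^2 / 2))
      expect_equal(p_spec, mean(x^2), tolerance = 0.01)
    }
  })
})

test_that("out-of-band interference contributes almost nothing to AMSA", {
  fs <- 250
  n <- 512
  t <- (0:(n - 1)) / fs
  f_in <- 20 * fs / n           # ~9.8 Hz, in band
  f_out <- 123 * fs / n         # ~60 Hz, out of band (bin-aligned, so the
                                # comparison isolates the filter response
                                # from rectangular-window leakage)
  a_in <- amsa_from_episode(ecg_episode(sin(2 * pi * f_in * t), fs))
  a_out <- amsa_from_episode(ecg_episode(sin(2 * pi * f_out * t), fs))
  expect_lt(a_out, 0.05 * a_in)
  expect_equal(amsa_from_episode(ecg_episode(rep(0, n), fs)), 0)
})
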