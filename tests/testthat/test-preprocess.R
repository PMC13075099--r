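test_that("polyphase doubling preserves length bookkeeping, timing and tones", {
  out <- resample_2x(rnorm(5000), 500)
  expect_equal(length(out$signal), 10000)
  expect_equal(out$fs, 1000)
  expect_error(resample_2x(numeric(0), 500), "empty")

  # an annotation keeps its physical time on the doubled grid
  expect_equal(map_indices_2x(1235L), 2469L)
  expect_equal((map_indices_2x(1235L) - 1) / 1000, (1235 - 1) / 500)

  # a 10 Hz tone survives with its frequency and amplitude
  fs <- 1000
  tt <- (0:4999) / fs
  tone <- sin(2 * pi * 10 * tt)
  up <- resample_2x(tone, fs)$signal
  sp <- Mod(fft(up))[1:5000]
  peak_hz <- (which.max(sp) - 1) * 2 * fs / length(up)
  expect_equal(peak_hz, 10, tolerance = 0.1)
  expect_lt(abs(max(abs(up[100:9900])) / max(abs(tone)) - 1), 0.01)
})

test_that("50 Hz notch removes the line tone and spares the ECG band", {
  fs <- 1000
  tt <- (0:9999) / fs
  x50 <- sin(2 * pi * 50 * tt)
  expect_lt(sd(notch_50(x50, fs)) / sd(x50), 0.1)
  x10 <- sin(2 * pi * 10 * tt)
  expect_lt(abs(sd(notch_50(x10, fs)) / sd(x10) - 1), 0.02)
  x90 <- sin(2 * pi * 90 * tt)
  gain_db <- 20 * log10(sd(notch_50(x90, fs)) / sd(x90))
  expect_lt(abs(gain_db), 1)
  expect_equal(notch_50(numeric(2000), fs), numeric(2000))
  expect_error(notch_50(rnorm(100), fs = 90), "100")
})

test_that("zero-phase bandpass removes DC, keeps in-band tones lag-free and attenuates out of band", {
  fs <- 1000
  tt <- (0:9999) / fs
  const <- rep(5, 10000)
  expect_lt(abs(mean(butter_bandpass_zerophase(const, fs, 0.1, 100))), 5e-3)

  x30 <- sin(2 * pi * 30 * tt)
  y30 <- butter_bandpass_zerophase(x30, fs, 10, 60)
  expect_lt(abs(sd(y30) / sd(x30) - 1), 0.05)
  lags <- -20:20
  xc <- vapply(lags, function(l) {
    idx <- 500:9500
    cor(x30[idx], y30[idx + l])
  }, numeric(1))
  expect_equal(lags[which.max(xc)], 0)

  x5 <- sin(2 * pi * 5 * tt)
  expect_lt(sd(butter_bandpass_zerophase(x5, fs, 10, 60)) / sd(x5), 0.3)
  expect_error(butter_bandpass_zerophase(x5, fs, 10, 600), "Nyquist")
})

test_that("standard preprocessing is linear, suppresses line interference and keeps peaks in place", {
  rec <- synth_clean_aecg(table1_cases()[1, ], 10, 500, seed = 2)
  pre <- preprocess_standard(rec)
  expect_identical(pre$fetal_rpeaks, rec$fetal_rpeaks)

  # linearity
  rec3 <- rec
  rec3$signal <- 3 * rec$signal
  expect_equal(preprocess_standard(rec3)$signal, 3 * pre$signal,
               tolerance = 1e-8)

  # 50 Hz interference is removed: output approximately equals that of the
  # clean signal
  # (compared over the central 80%; the residual is dominated by finite-window
  # transients of the zero-phase chain, at the same level as reference
  # forward-backward implementations, not by leakage of the 50 Hz tone)
  tt <- (seq_along(rec$signal) - 1) / rec$fs
  hum <- rec
  hum$signal <- rec$signal + 0.5 * sin(2 * pi * 50 * tt)
  mid <- seq(round(0.1 * length(tt)), round(0.9 * length(tt)))
  expect_lt(sd((preprocess_standard(hum)$signal - pre$signal)[mid]) /
              sd(pre$signal[mid]), 0.15)

  # fetal-only record: annotations stay on local extrema of the filtered trace
  frec <- synth_clean_aecg(list(case_id = 90, m_hr = 80, m_amp = 0,
                                f_hr = 140, f_amp = 0.3), 10, 500, seed = 3)
  fpre <- preprocess_standard(frec)
  for (p in frec$fetal_rpeaks[-c(1, length(frec$fetal_rpeaks))]) {
    w <- (p - 10):(p + 10)
    expect_lte(abs(w[which.max(abs(fpre$signal[w]))] - p), 3)
  }
})
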