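test_that("simulator case grid matches the printed parameter table", {
  tab <- table1_cases()
  expect_equal(nrow(tab), 15)
  expect_equal(unlist(tab[1, c("m_hr", "m_amp", "f_hr", "f_amp", "ratio")],
                      use.names = FALSE), c(80, 0.35, 140, 0.30, 1.17))
  expect_equal(unlist(tab[5, c("m_hr", "m_amp", "f_hr", "f_amp", "ratio")],
                      use.names = FALSE), c(85, 0.80, 162, 0.05, 16.0))
  expect_equal(which(tab$f_amp < 0.10), c(4, 5, 8, 10, 13))
  # stated ratio consistent with the amplitude columns within 5%
  expect_true(all(abs(tab$m_amp / tab$f_amp - tab$ratio) / tab$ratio < 0.05))
  expect_true(all(tab$m_hr >= 60 & tab$m_hr <= 120))
  expect_true(all(tab$f_hr >= 110 & tab$f_hr <= 162))
  expect_true(all(tab$m_amp > 0 & tab$f_amp > 0))
  expect_equal(range(tab$ratio), c(1.17, 16.0))
})

test_that("clean synthesis honors heart rates, annotations and determinism", {
  rec <- synth_clean_aecg(table1_cases()[1, ], duration_s = 10, fs = 500,
                          seed = 1)
  expect_s3_class(rec, "aecg")
  expect_equal(length(rec$signal), 5000)
  expect_true(length(rec$fetal_rpeaks) %in% c(23, 24)) # 140 bpm over 10 s
  expect_true(length(rec$maternal_rpeaks) %in% c(13, 14)) # 80 bpm over 10 s
  expect_equal(rec$signal, rec$maternal_clean + rec$fetal_clean)
  expect_true(all(diff(rec$fetal_rpeaks) > 0))
  expect_true(all(rec$fetal_rpeaks >= 1 & rec$fetal_rpeaks <= 5000))

  # every annotation sits on a local maximum of its clean component
  for (p in rec$fetal_rpeaks) {
    w <- max(1, p - 10):min(5000, p + 10)
    expect_lte(abs(w[which.max(rec$fetal_clean[w])] - p), 2)
  }

  # jitter-free synthesis is exactly periodic at the rounded RR
  flat <- synth_clean_aecg(table1_cases()[1, ], 10, 500, seed = 1,
                           rr_jitter = 0, amp_jitter = 0)
  expect_true(all(diff(flat$fetal_rpeaks) == round(500 * 60 / 140)))
  expect_true(all(diff(flat$maternal_rpeaks) == round(500 * 60 / 80)))

  again <- synth_clean_aecg(table1_cases()[1, ], 10, 500, seed = 1)
  expect_identical(rec$signal, again$signal)
  expect_identical(rec$fetal_rpeaks, again$fetal_rpeaks)

  expect_error(synth_clean_aecg(table1_cases()[1, ], -1, 500), "positive")
  expect_error(synth_clean_aecg(table1_cases()[1, ], 10, 100), "250")
})

test_that("noise augmentation hits the SNR target exactly and leaves annotations alone", {
  rec <- synth_clean_aecg(table1_cases()[3, ], 10, 500, seed = 4)
  noisy <- add_noise(rec, noise_spec(seed = 7))
  snr <- 10 * log10(sum(rec$signal^2) / sum((noisy$signal - rec$signal)^2))
  expect_lt(abs(snr - 10), 1e-6)
  expect_identical(noisy$fetal_rpeaks, rec$fetal_rpeaks)
  expect_identical(noisy$maternal_rpeaks, rec$maternal_rpeaks)
  expect_identical(noisy$fetal_clean, rec$fetal_clean)

  # a 60 dB target leaves one millionth of the clean power as noise
  quiet <- add_noise(rec, noise_spec(target_snr_db = 60, seed = 7))
  expect_lt(abs(sum((quiet$signal - rec$signal)^2) / sum(rec$signal^2) - 1e-6),
            1e-8)

  again <- add_noise(rec, noise_spec(seed = 7))
  expect_identical(noisy$signal, again$signal)

  flat <- rec
  flat$signal <- rep(1, length(rec$signal))
  expect_error(add_noise(flat, noise_spec(seed = 1)), "constant")
})

test_that("generator draws do not disturb the caller's RNG stream", {
  set.seed(42)
  a <- rnorm(3)
  set.seed(42)
  invisible(synth_clean_aecg(table1_cases()[2, ], 5, 500, seed = 9))
  b <- rnorm(3)
  expect_identical(a, b)
})
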