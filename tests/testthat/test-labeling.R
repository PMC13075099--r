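test_that("reference fetal peaks are recovered from a clean fetal lead", {
  rec <- synth_clean_aecg(list(case_id = 91, m_hr = 80, m_amp = 0,
                               f_hr = 140, f_amp = 0.3), 10, 1000, seed = 6)
  det <- detect_reference_fpeaks(rec$fetal_clean, 1000)
  expect_lte(abs(length(det) - length(rec$fetal_rpeaks)), 1)
  m <- match_rpeaks(det, rec$fetal_rpeaks, fs = 1000, tol_s = 0.01)
  expect_gte(m$recall, (length(rec$fetal_rpeaks) - 1) / length(rec$fetal_rpeaks))

  # refractory rule: of two candidate maxima 200 ms apart only the larger survives
  x <- numeric(5000)
  x[1000] <- 1
  x[1200] <- 0.6
  x[3000] <- 1
  det2 <- fecgeemd:::.peaks_above(x, 0.5, min_dist = 300)
  expect_true(1000 %in% det2)
  expect_false(1200 %in% det2)

  expect_equal(detect_reference_fpeaks(numeric(5000), 1000), integer(0))
})

test_that("the labeling rule follows its definition on canonical inputs", {
  # no reference peaks -> negative by default
  expect_equal(label_imf(rnorm(1000), integer(0)), 0L)

  # a clean pulse train concentrated at the R-peaks is positive
  pulses <- numeric(10000)
  rp <- seq(300, 9700, by = 430)
  for (p in rp) pulses[p + (-5:5)] <- dnorm(-5:5, sd = 2) * 10
  expect_equal(label_imf(pulses, rp, 50), 1L)
  expect_equal(label_imf(pulses, rp, 50, statistic = "median"), 1L)

  # white noise unrelated to the peaks is negative nearly always under the
  # median statistic (the stated motivation for using it)
  set.seed(9)
  zero_frac <- mean(vapply(1:200, function(i) {
    v <- rnorm(10000)
    rp <- sort(sample(200:9800, 23))
    label_imf(v, rp, 50, statistic = "median") == 0L
  }, logical(1)))
  expect_gte(zero_frac, 0.95)
})

test_that("labeling agrees with a naive loop oracle and is scale invariant", {
  set.seed(17)
  for (statistic in c("max", "median")) {
    mismatch <- 0L
    for (i in 1:500) {
      n <- sample(200:600, 1)
      v <- rnorm(n) + (runif(1) < 0.5) * 3 *
        sin(2 * pi * 30 * seq(0, 1, length.out = n))
      rp <- sort(sample(seq_len(n), sample(0:8, 1)))
      hw <- sample(5:50, 1)
      a <- label_imf(v, rp, hw, statistic)
      b <- ref_label_imf(v, rp, hw, statistic)
      mismatch <- mismatch + (a != b)
    }
    expect_equal(mismatch, 0L)
  }

  # both thresholds scale with the waveform, so labels are scale invariant
  set.seed(23)
  for (i in 1:50) {
    v <- rnorm(500)
    rp <- sort(sample(50:450, 5))
    expect_equal(label_imf(v, rp, 20), label_imf(17.3 * v, rp, 20))
  }
})

test_that("the median statistic shrugs off one contaminated beat window", {
  set.seed(41)
  v <- rnorm(10000) # negative IMF: noise unrelated to the peaks
  rp <- seq(500, 9500, by = 430)
  stopifnot(label_imf(v, rp, 50, statistic = "median") == 0L)
  v_spiked <- v
  v_spiked[rp[3] + (-3:3)] <- 50 # huge burst inside a single window
  expect_equal(label_imf(v_spiked, rp, 50, statistic = "median"), 0L)
})

test_that("dataset construction is bounded, deterministic and balanced", {
  cases <- smoke_cases()[c(1, 6, 12)]
  ds <- build_labeled_dataset(cases, eemd_config(seed = 11))
  n_seg <- sum(vapply(cases, function(r)
    length(r$signal) %/% (10 * r$fs), numeric(1)))
  expect_lte(nrow(ds$meta), n_seg * 8)
  expect_true(all(ds$meta$label %in% c(0L, 1L)))
  expect_true(all(ds$meta$imf_index >= 1 & ds$meta$imf_index <= 8))
  ds2 <- build_labeled_dataset(cases, eemd_config(seed = 11))
  expect_identical(ds$meta, ds2$meta)

  bad <- cases[[1]]
  bad$fetal_rpeaks <- integer(0)
  expect_error(build_labeled_dataset(list(bad)), "annotation")
})

test_that("positive prevalence on the full study grid is moderate", {
  ds <- smoke_dataset()
  frac <- mean(ds$meta$label)
  expect_gte(frac, 0.2)
  expect_lte(frac, 0.7)
})
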