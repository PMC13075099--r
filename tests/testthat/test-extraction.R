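test_that("maternal R-peaks are detected near truth on synthetic mixtures", {
  rec <- synth_clean_aecg(table1_cases()[1, ], 10, 500, seed = 21)
  pre <- preprocess_standard(rec)
  det <- detect_maternal_rpeaks(pre$signal, 500)
  expect_lte(abs(length(det) - length(rec$maternal_rpeaks)), 1)
  m <- match_rpeaks(det, rec$maternal_rpeaks, fs = 500, tol_s = 0.02)
  expect_gte(m$recall, (length(rec$maternal_rpeaks) - 1) /
               length(rec$maternal_rpeaks))
  expect_equal(length(detect_maternal_rpeaks(numeric(5000), 500)), 0)
})

test_that("the fallback detector enforces the 500 ms refractory rule", {
  fs <- 500
  x <- numeric(10 * fs) # 3 sparse beats: primary declares failure
  x[round(c(1.0, 5.0, 9.0) * fs)] <- 1
  x[round(1.4 * fs)] <- 0.6 # a competing maximum 400 ms after the first
  det <- detect_maternal_rpeaks(x, fs)
  expect_equal(attr(det, "method"), "fallback")
  expect_true(round(1.0 * fs) %in% det)
  expect_false(round(1.4 * fs) %in% det)
})

test_that("coherent averaging recovers the beat and obeys the averaging law", {
  beat <- dnorm(seq(-3, 3, length.out = 61))
  x <- as.numeric(sapply(1:20, function(i) c(beat, numeric(89))))
  rp <- seq(31, by = 150, length.out = 20)
  tmpl <- build_maternal_template(x, rp, 30)
  expect_equal(as.numeric(tmpl), beat, tolerance = 1e-12)
  expect_equal(attr(tmpl, "n_beats"), 20L)

  # mean over N noisy beats suppresses noise like 1/sqrt(N)
  set.seed(10)
  sigma <- 0.5
  xn <- numeric(100 * 150 + 60)
  rp2 <- seq(31, by = 150, length.out = 100)
  for (p in rp2) xn[p + (-30:30)] <- beat + rnorm(61, sd = sigma)
  t2 <- build_maternal_template(xn, rp2, 30)
  expect_lt(sqrt(mean((as.numeric(t2) - beat)^2)), 0.15 * sigma)

  # a beat whose window leaves the record is excluded
  t3 <- build_maternal_template(xn, c(10L, rp2), 300)
  expect_lt(attr(t3, "n_beats"), length(rp2) + 1)

  expect_error(build_maternal_template(x, c(31L), 30), "degenerate")
})

test_that("template subtraction cancels periodic beats and enhances the fetal part", {
  beat <- dnorm(seq(-3, 3, length.out = 61))
  x <- numeric(3000)
  rp <- seq(100, 2900, by = 150)
  for (p in rp) x[p + (-30:30)] <- x[p + (-30:30)] + beat
  resid <- subtract_maternal(x, build_maternal_template(x, rp, 40), rp)
  expect_lt(sd(resid) / sd(x), 0.05)

  rec <- synth_clean_aecg(table1_cases()[2, ], 10, 500, seed = 33)
  pre <- preprocess_standard(rec)
  mp <- detect_maternal_rpeaks(pre$signal, 500)
  tm <- build_maternal_template(pre$signal, mp, round(0.25 * 500))
  r <- subtract_maternal(pre$signal, tm, mp)
  expect_gt(abs(cor(r, rec$fetal_clean)), abs(cor(pre$signal, rec$fetal_clean)))

  expect_identical(subtract_maternal(x, build_maternal_template(x, rp, 40),
                                     integer(0)), x)
})

test_that("top-k selection ranks by score with deterministic tie breaks", {
  waves <- list(rep(1, 10), rep(2, 10), rep(4, 10), rep(8, 10))
  expect_equal(select_top_k(waves, c(0.9, 0.8, 0.1, 0.05), 2), rep(3, 10))
  expect_equal(select_top_k(waves, c(0.1, 0.7, 0.2, 0.7), 1), rep(2, 10))
  expect_warning(out <- select_top_k(waves, c(1, 2, 3, 4), 9), "all")
  expect_equal(out, rep(15, 10))

  # completeness: all IMFs reconstruct signal minus residual exactly
  x <- sin(2 * pi * 25 * (0:999) / 250) + 0.5 * sin(2 * pi * 2 * (0:999) / 250)
  d <- emd(x, 8, fs = 250)
  expect_equal(select_top_k(d, seq_along(d$imfs), length(d$imfs)),
               x - d$residual, tolerance = 1e-10)
})

test_that("heuristic scores favour in-band, reference-shaped IMFs", {
  fs <- 250
  tt <- (0:2499) / fs
  ref <- sin(2 * pi * 30 * tt)
  iset <- structure(list(imfs = list(sin(2 * pi * 30 * tt),
                                     sin(2 * pi * 2 * tt)),
                         residual = numeric(2500), fs = fs,
                         source_span = c(1, 2500)), class = "imf_set")
  sc <- auto_select_scores(iset, ref)
  expect_gt(sc[1], sc[2])
  expect_equal(sc[1], 1) # identical (after filtering) to the reference
})

test_that("oracle scores equal unit correlation on truth and vanish on noise", {
  set.seed(77)
  truth <- sin(2 * pi * 30 * (0:9999) / 1000)
  expect_equal(oracle_select_scores(list(truth), truth), 1)
  expect_lt(oracle_select_scores(list(rnorm(10000)), truth), 0.1)
  expect_error(oracle_select_scores(list(truth), NULL), "unavailable")
})

test_that("oracle-guided extraction of a clean strong-fetal case is faithful", {
  rec <- synth_clean_aecg(table1_cases()[1, ], 20, 250, seed = 44)
  cfg <- extraction_config(selection_mode = "oracle",
                           eemd = eemd_config(seed = 2))
  res <- extract_fecg(rec, cfg = cfg)
  ref <- butter_bandpass_zerophase(rec$fetal_clean, 250, 10, 60, 4)
  expect_gt(abs(as.numeric(correlation_cc(ref, res$fecg, 250))), 0.9)
  expect_equal(length(res$fecg), length(rec$signal))
  expect_true(all(diff(res$fetal_rpeaks) > 0))

  res2 <- extract_fecg(rec, cfg = cfg)
  expect_identical(res$fecg, res2$fecg)
  expect_identical(res$fetal_rpeaks, res2$fetal_rpeaks)

  expect_error(extract_fecg(rec, cfg = extraction_config(selection_mode = "cnn")),
               "model")
  plain <- rec
  plain$fetal_clean <- NULL
  expect_error(extract_fecg(plain, cfg = cfg), "ground truth")
})

test_that("each pipeline stage improves the median fetal correlation", {
  ccs <- sapply(smoke_cases()[c(1, 6, 9, 12, 14)], function(rec) {
    cfg <- extraction_config(selection_mode = "oracle",
                             eemd = eemd_config(seed = 3))
    res <- extract_fecg(rec, cfg = cfg)
    ref <- butter_bandpass_zerophase(rec$fetal_clean, rec$fs, 10, 60, 4)
    cc <- function(v) abs(as.numeric(correlation_cc(ref, v, rec$fs)))
    c(raw = cc(rec$signal), resid = cc(res$residual),
      stage1 = cc(res$stage1_estimate), final = cc(res$fecg))
  })
  med <- apply(ccs, 1, median)
  expect_lt(med["raw"], med["resid"])
  expect_lt(med["resid"], med["stage1"])
  expect_lte(med["stage1"], med["final"] + 0.02)
})
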