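test_that("parameter counts reconcile with the closed-form layer sums", {
  # default pyramid architecture prints as 5.91 M
  expect_equal(count_parameters(classifier_spec()), 5905793L)
  expect_equal(round(count_parameters(classifier_spec()) / 1e6, 2), 5.91)

  # the architecture-variant grid: printed millions per configuration
  variants <- list(
    narrow = list(ch = c(16, 32, 64, 128, 256), printed = 2.72),
    uniform = list(ch = rep(64, 5), printed = 1.01),
    wide = list(ch = c(64, 128, 256, 512, 1024), printed = 14.44),
    bottleneck = list(ch = c(64, 32, 64, 128, 256), printed = 2.76))
  for (v in variants) {
    n <- count_parameters(classifier_spec(channels = v$ch))
    expect_lt(abs(n / 1e6 - v$printed) / v$printed, 0.02)
  }

  # kernel-size rearrangements keep the count unchanged
  for (k in list(c(7, 11, 15, 21, 31), c(15, 15, 15, 11, 7),
                 c(21, 15, 11, 15, 21))) {
    expect_equal(count_parameters(classifier_spec(kernel_sizes = k)),
                 count_parameters(classifier_spec(
                   kernel_sizes = c(31, 21, 15, 11, 7),
                   channels = c(32, 64, 128, 256, 512))) -
                   sum((c(31, 21, 15, 11, 7) - k) *
                         c(1, 32, 64, 128, 256) * c(32, 64, 128, 256, 512)))
  }

  # halving channels strictly reduces the count
  expect_lt(count_parameters(classifier_spec(channels = c(16, 32, 64, 128, 256))),
            count_parameters(classifier_spec()))

  # the analytic count matches the instantiated weight arrays
  m <- build_classifier(classifier_spec(input_len = 640L), seed = 1)
  expect_equal(count_parameters(m), count_parameters(m$spec))

  expect_error(classifier_spec(kernel_sizes = c(31, 21)), "length 5")
  expect_error(classifier_spec(fc_dims = c(64, 32, 2)), "final width")
})

test_that("IMF resampling to the model input length preserves tones", {
  v <- rnorm(10000)
  expect_identical(resample_to_input_len(v, 10000L), v)
  short <- rnorm(2500)
  expect_equal(length(resample_to_input_len(short, 10000L)), 10000)

  fs <- 250
  tone <- sin(2 * pi * 25 * (0:2499) / fs)
  up <- resample_to_input_len(tone, 10000L)
  sp <- Mod(fft(up))[1:5000]
  peak_hz <- (which.max(sp) - 1) * 1000 / length(up)
  expect_equal(peak_hz, 25, tolerance = 0.2)
})

test_that("an untrained scorer produces deterministic probabilities in (0,1)", {
  spec <- classifier_spec(input_len = 640L)
  m <- build_classifier(spec, seed = 3)
  z <- fecgeemd:::cnn_forward_cpp(m$weights, spec$kernel_sizes, spec$channels,
                                  spec$input_len, spec$adaptive_out_len,
                                  spec$fc_dims, spec$first_stride, 0L,
                                  matrix(0, 1, 640))
  expect_true(is.finite(z))

  imfs <- lapply(1:4, function(i) rnorm(640))
  p1 <- score_imfs(m, imfs)
  p2 <- score_imfs(m, imfs)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_length(p1, 4)
})

test_that("negative resampling approaches the 2:1 target from below", {
  set.seed(8)
  for (i in 1:20) {
    n_pos <- sample(5:60, 1)
    n_neg <- sample(5:200, 1)
    labels <- c(rep(1, n_pos), rep(0, n_neg))
    rows <- fecgeemd:::.balance_rows(labels, 2, seed = i)
    kept <- labels[rows]
    if (n_neg >= 2 * n_pos)
      expect_lte(abs(sum(kept == 0) / sum(kept == 1) - 2), 1 / n_pos)
    else
      expect_equal(sum(kept == 0), n_neg) # too few negatives: keep them all
    expect_equal(sum(kept == 1), n_pos)
  }
})

test_that("training minimizes the logit cross-entropy and is seed deterministic", {
  # synthetic IMF-like task: positives carry a quasi-periodic 30 Hz burst
  set.seed(77)
  n <- 60
  len <- 640L
  tt <- (0:(len - 1)) / 64
  X <- lapply(1:n, function(i) rnorm(len))
  y <- rep(c(0L, 1L), length.out = n)
  for (i in which(y == 1))
    X[[i]] <- 0.4 * X[[i]] + 3 * sin(2 * pi * 30 * tt) * (sin(2 * pi * 1.7 * tt) > 0.7)
  ds <- list(meta = data.frame(subject_id = "s", segment_index = 1,
                               imf_index = 1, label = y), waveforms = X)
  spec <- classifier_spec(input_len = len)
  cfg <- train_config(epochs = 4, seeds = 1L)
  m <- train_fold(ds, spec, cfg, seed = 5)
  loss <- attr(m, "loss")
  # binary cross-entropy at near-zero logits starts around ln 2
  expect_lt(abs(loss[1] - log(2)), 0.2)
  expect_lt(loss[length(loss)], loss[1])

  # learned separation on the training distribution
  p <- score_imfs(m, X)
  expect_gt(mean(p[y == 1]), mean(p[y == 0]))

  m2 <- train_fold(ds, spec, cfg, seed = 5)
  expect_identical(m$weights, m2$weights)

  ds_one <- ds
  ds_one$meta$label <- 1L
  expect_error(train_fold(ds_one, spec, cfg), "single class")
})

test_that("rank AUC matches pairwise counting and falls back to one half", {
  expect_equal(roc_auc_safe(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc_safe(c(1, 1, 1), c(0.2, 0.5, 0.9)), 0.5)
  expect_equal(roc_auc_safe(c(1, 0, 1, 0), rep(0.6, 4)), 0.5)
  expect_error(roc_auc_safe(numeric(0), numeric(0)), "empty")

  set.seed(12)
  for (i in 1:500) {
    n <- sample(2:30, 1)
    labels <- rbinom(n, 1, 0.5)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
    expect_equal(roc_auc_safe(labels, scores), ref_auc(labels, scores))
  }
})

test_that("leave-one-subject-out folds have the contracted shape", {
  set.seed(55)
  len <- 640L
  tt <- (0:(len - 1)) / 64
  mk_subj <- function(id, n = 12) {
    X <- lapply(1:n, function(i) rnorm(len))
    y <- rep(c(0L, 1L), length.out = n)
    for (i in which(y == 1))
      X[[i]] <- 0.4 * X[[i]] + 3 * sin(2 * pi * 25 * tt) *
        (sin(2 * pi * 2.1 * tt) > 0.7)
    list(meta = data.frame(subject_id = id, segment_index = 1,
                           imf_index = seq_len(n), label = y), waveforms = X)
  }
  subs <- lapply(c("a", "b", "c"), mk_subj)
  ds <- list(meta = do.call(rbind, lapply(subs, `[[`, "meta")),
             waveforms = do.call(c, lapply(subs, `[[`, "waveforms")))
  cv <- loso_cv(ds, classifier_spec(input_len = len),
                train_config(epochs = 2, seeds = c(1L, 2L)))
  expect_equal(nrow(cv$folds), 3 * 2) # subjects x runs
  expect_setequal(unique(cv$folds$held_out_subject), c("a", "b", "c"))
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
  expect_equal(sort(names(cv$models)), c("a", "b", "c"))
  expect_error(loso_cv(subs[[1]], classifier_spec(input_len = len)),
               "2 subjects")
})
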