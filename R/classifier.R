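#' IMF classifier architecture specification
#'
#' Five convolution--batch-norm--ReLU--pool blocks followed by three fully
#' connected layers producing one logit. Kernel sizes decrease with depth so
#' early layers see low-frequency (maternal) structure and deep layers the
#' higher-frequency fetal QRS content; channels grow 32 to 512; the first
#' convolution uses stride 2; blocks 1--4 max-pool by 2 and block 5 is
#' adaptively average-pooled to `adaptive_out_len` time steps (hybrid
#' pooling), making the flattened feature size independent of `input_len`.
#'
#' @param kernel_sizes Integer vector of 5 kernel lengths.
#' @param channels Integer vector of 5 channel counts.
#' @param input_len Expected IMF length in samples (default 10000 = 10 s at
#'   1000 Hz).
#' @param adaptive_out_len Adaptive pooling output length (default 8).
#' @param fc_dims The three fully connected widths (default 1024, 256, 1).
#' @param first_stride Stride of the first convolution (default 2).
#' @param pooling `"hybrid"` (default), `"pure_max"` or `"pure_adaptive"`.
#' @param dropout Dropout rate between fully connected layers (default 0.5).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kernel_sizes = c(31L, 21L, 15L, 11L, 7L),
                            channels = c(32L, 64L, 128L, 256L, 512L),
                            input_len = 10000L, adaptive_out_len = 8L,
                            fc_dims = c(1024L, 256L, 1L), first_stride = 2L,
                            pooling = c("hybrid", "pure_max", "pure_adaptive"),
                            dropout = 0.5) {
  pooling <- match.arg(pooling)
  if (length(kernel_sizes) != 5) stop("kernel_sizes must have length 5")
  if (length(channels) != 5) stop("channels must have length 5")
  if (length(fc_dims) != 3 || fc_dims[3] != 1)
    stop("fc_dims must have length 3 with a final width of 1")
  if (input_len < 16) stop("input_len must be at least 16")
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 channels = as.integer(channels),
                 input_len = as.integer(input_len),
                 adaptive_out_len = as.integer(adaptive_out_len),
                 fc_dims = as.integer(fc_dims),
                 first_stride = as.integer(first_stride),
                 pooling = pooling, dropout = dropout),
            class = "classifier_spec")
}

.pooling_code <- function(p) match(p, c("hybrid", "pure_max", "pure_adaptive")) - 1L

#' Instantiate the IMF classifier
#'
#' Builds the network of a [classifier_spec()] with seeded random weights.
#'
#' @param spec A [classifier_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `imf_classifier` holding `spec`, `weights` and a
#'   `trained` flag.
#' @export
build_classifier <- function(spec = classifier_spec(), seed = 1) {
  w <- cnn_init_cpp(spec$kernel_sizes, spec$channels, spec$input_len,
                    spec$adaptive_out_len, spec$fc_dims, spec$first_stride,
                    .pooling_code(spec$pooling), as.integer(seed))
  structure(list(spec = spec, weights = w, trained = FALSE),
            class = "imf_classifier")
}

#' Count trainable parameters
#'
#' Counts every trainable scalar: convolution weights and biases, batch-norm
#' scale and shift, and fully connected weights and biases. Batch-norm
#' running statistics are not trainable and are excluded. For the default
#' architecture this is 5,905,793, reported as 5.91 million.
#'
#' @param model An `imf_classifier` or a [classifier_spec()] (counted
#'   analytically).
#' @return Integer parameter count.
#' @export
#' @examples
#' round(count_parameters(classifier_spec()) / 1e6, 2)
count_parameters <- function(model) {
  spec <- if (inherits(model, "imf_classifier")) model$spec else model
  ch <- spec$channels
  k <- spec$kernel_sizes
  cin <- c(1L, ch[-5])
  conv <- sum(cin * ch * k + ch)
  bn <- 2L * sum(ch)
  fin <- c(ch[5] * spec$adaptive_out_len, spec$fc_dims[1], spec$fc_dims[2])
  fc <- sum(fin * spec$fc_dims + spec$fc_dims)
  total <- conv + bn + fc
  if (inherits(model, "imf_classifier")) {
    w <- model$weights
    actual <- sum(vapply(w$conv_w, length, 0)) + sum(vapply(w$conv_b, length, 0)) +
      sum(vapply(w$gamma, length, 0)) + sum(vapply(w$beta, length, 0)) +
      sum(vapply(w$fc_w, length, 0)) + sum(vapply(w$fc_b, length, 0))
    stopifnot(actual == total)
  }
  as.integer(total)
}

#' Resample an IMF to the classifier input length
#'
#' Linear-phase resampling to exactly `input_len` samples, used only for
#' scoring; reconstruction always uses the original IMFs at the original
#' sampling rate.
#'
#' @param imf Numeric vector, length >= 16.
#' @param input_len Target length (default 10000).
#' @return Numeric vector of length `input_len`.
#' @export
resample_to_input_len <- function(imf, input_len = 10000L) {
  n <- length(imf)
  if (n < 16) stop("IMF too short")
  if (n == input_len) return(imf)
  if (input_len > n) {
    # upsample: bandlimited-ish via FFT zero padding would ring at edges;
    # cubic interpolation preserves tones up to the original Nyquist well
    stats::spline(x = seq(0, 1, length.out = n), y = imf,
                  xout = seq(0, 1, length.out = input_len))$y
  } else {
    # low-pass first to avoid aliasing, then interpolate
    ratio <- input_len / n
    bf <- signal::butter(4, 0.98 * ratio, type = "low")
    f <- .filtfilt_pad(bf$b, bf$a, imf)
    stats::approx(x = seq(0, 1, length.out = n), y = f,
                  xout = seq(0, 1, length.out = input_len))$y
  }
}

#' Score IMFs with the classifier
#'
#' Each IMF is z-scored (amplitude carries no class information by design of
#' the scale-invariant labels), resampled to the model input length, and
#' passed through the network; the sigmoid of the logit is the fetal-related
#' probability.
#'
#' @param model An `imf_classifier`.
#' @param imfs An `imf_set` or list of numeric vectors.
#' @return Numeric vector of probabilities in (0, 1), one per IMF.
#' @export
score_imfs <- function(model, imfs) {
  waves <- if (inherits(imfs, "imf_set")) imfs$imfs else imfs
  if (length(waves) == 0) return(numeric(0))
  X <- t(vapply(waves, function(v) {
    s <- stats::sd(v)
    v <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    resample_to_input_len(v, model$spec$input_len)
  }, numeric(model$spec$input_len)))
  z <- cnn_forward_cpp(model$weights, model$spec$kernel_sizes,
                       model$spec$channels, model$spec$input_len,
                       model$spec$adaptive_out_len, model$spec$fc_dims,
                       model$spec$first_stride,
                       .pooling_code(model$spec$pooling), X)
  1 / (1 + exp(-z))
}

#' Training configuration
#'
#' Adam with learning rate 1e-4 and weight decay 5e-4, batch size 64,
#' 60 epochs, negatives resampled to twice the positives, and 3 runs with
#' different seeds per cross-validation fold.
#'
#' @param lr Learning rate.
#' @param weight_decay L2 weight decay coupled into the Adam gradient.
#' @param batch_train,batch_val Batch sizes.
#' @param epochs Training epochs per fold.
#' @param neg_pos_ratio Target negatives-per-positive after resampling.
#' @param seeds Integer seeds, one per run.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 5e-4, batch_train = 64,
                         batch_val = 128, epochs = 60, neg_pos_ratio = 2,
                         seeds = c(1L, 2L, 3L)) {
  stopifnot(lr > 0, weight_decay >= 0, batch_train >= 1, epochs >= 1,
            neg_pos_ratio > 0, length(seeds) >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_train = as.integer(batch_train),
                 batch_val = as.integer(batch_val),
                 epochs = as.integer(epochs), neg_pos_ratio = neg_pos_ratio,
                 runs = length(seeds), seeds = as.integer(seeds)),
            class = "train_config")
}

# 2:1 negative resampling: subsample negatives without replacement down to
# neg_pos_ratio x positives; fewer negatives than the target are all kept
.balance_rows <- function(labels, ratio, seed) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  n_target <- round(ratio * length(pos))
  keep_neg <- if (length(neg) > n_target) {
    .with_seed(seed, sort(sample(neg, n_target)))
  } else neg
  sort(c(pos, keep_neg))
}

#' Train the classifier on labeled IMFs
#'
#' Negatives are subsampled (without replacement when possible) to
#' `neg_pos_ratio` times the positives, inputs are z-scored and resampled to
#' the model input length, and the network is optimized on binary
#' cross-entropy with logits. Deterministic given `seed`.
#'
#' @param dataset A labeled dataset from [build_labeled_dataset()] (or a list
#'   with `meta$label` and `waveforms`).
#' @param spec A [classifier_spec()].
#' @param cfg A [train_config()].
#' @param seed Integer seed controlling initialization, resampling, batch
#'   order and dropout.
#' @return A trained `imf_classifier` with a `loss` attribute (per-epoch
#'   mean training loss).
#' @export
train_fold <- function(dataset, spec = classifier_spec(), cfg = train_config(),
                       seed = 1) {
  labels <- dataset$meta$label
  if (all(labels == 1) || all(labels == 0))
    stop("training set contains a single class; cannot fit a binary scorer")
  rows <- .balance_rows(labels, cfg$neg_pos_ratio, derive_seed(seed, "balance"))
  X <- t(vapply(dataset$waveforms[rows], function(v) {
    s <- stats::sd(v)
    v <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    resample_to_input_len(v, spec$input_len)
  }, numeric(spec$input_len)))
  y <- as.numeric(labels[rows])
  model <- build_classifier(spec, seed = derive_seed(seed, "init"))
  out <- cnn_train_cpp(model$weights, spec$kernel_sizes, spec$channels,
                       spec$input_len, spec$adaptive_out_len, spec$fc_dims,
                       spec$first_stride, .pooling_code(spec$pooling),
                       X, y, cfg$epochs, cfg$batch_train, cfg$lr,
                       cfg$weight_decay, spec$dropout,
                       derive_seed(seed, "sgd"))
  model$weights <- out$weights
  model$trained <- TRUE
  attr(model, "loss") <- as.numeric(out$loss)
  model
}

#' Rank-based AUC with a single-class fallback
#'
#' Standard pairwise (Mann--Whitney) AUC with ties counted one half. A
#' validation set containing only one class returns exactly 0.5.
#'
#' @param labels Vector of 0/1 labels.
#' @param scores Numeric scores, same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc_safe <- function(labels, scores) {
  if (length(labels) == 0) stop("empty input")
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(0.5)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Leave-one-subject-out cross-validation
#'
#' Per subject: hold out all of its IMFs, train `cfg$runs` models on the
#' remaining subjects (one per seed in `cfg$seeds`), and evaluate
#' [roc_auc_safe()] on the held-out IMFs.
#'
#' @param dataset A labeled dataset from [build_labeled_dataset()].
#' @param spec A [classifier_spec()].
#' @param cfg A [train_config()].
#' @param keep_models Keep each fold's first-run model in the result
#'   (default TRUE; used by the extraction pipeline so each record is scored
#'   by a model that never saw it).
#' @return A list with `folds` (data.frame: `held_out_subject`, `run`,
#'   `seed`, `auc`, `n_val_imfs`, `n_val_pos`), `mean_auc`, `sd_auc`, and
#'   `models` (named by held-out subject) when `keep_models`.
#' @export
loso_cv <- function(dataset, spec = classifier_spec(), cfg = train_config(),
                    keep_models = TRUE) {
  subjects <- unique(dataset$meta$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects for LOSO")
  folds <- list()
  models <- list()
  for (subj in subjects) {
    val_idx <- which(dataset$meta$subject_id == subj)
    train_idx <- setdiff(seq_len(nrow(dataset$meta)), val_idx)
    if (length(val_idx) == 0) {
      warning(sprintf("subject %s has no IMFs; excluded", subj))
      next
    }
    train_set <- list(meta = dataset$meta[train_idx, , drop = FALSE],
                      waveforms = dataset$waveforms[train_idx])
    for (r in seq_len(cfg$runs)) {
      model <- train_fold(train_set, spec, cfg,
                          seed = derive_seed(cfg$seeds[r], subj))
      scores <- score_imfs(model, dataset$waveforms[val_idx])
      auc <- roc_auc_safe(dataset$meta$label[val_idx], scores)
      folds[[length(folds) + 1L]] <- data.frame(
        held_out_subject = subj, run = r, seed = cfg$seeds[r], auc = auc,
        n_val_imfs = length(val_idx),
        n_val_pos = sum(dataset$meta$label[val_idx]),
        stringsAsFactors = FALSE)
      if (keep_models && r == 1L) models[[subj]] <- model
    }
  }
  folds <- do.call(rbind, folds)
  out <- list(folds = folds, mean_auc = mean(folds$auc), sd_auc = sd(folds$auc))
  if (keep_models) out$models <- models
  out
}

#' @export
print.imf_classifier <- function(x, ...) {
  cat(sprintf("<imf_classifier> %s pooling, input %d, %s params, %s\n",
              x$spec$pooling, x$spec$input_len,
              format(count_parameters(x), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}
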