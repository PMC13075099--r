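#' EEMD configuration
#'
#' Defaults follow the fixed decomposition setup used throughout the
#' pipeline: ensemble size 30, added-noise level 0.2 times the signal
#' standard deviation, and at most 8 intrinsic mode functions per segment.
#' Sifting stops on the Cauchy criterion (threshold `sd_thresh`) or after
#' `max_sift` passes.
#'
#' @param ensemble_size Number of noise-perturbed decompositions (default 30).
#' @param noise_width Added white-noise standard deviation as a fraction of
#'   the signal standard deviation (default 0.2).
#' @param max_imfs Maximum number of IMFs (default 8).
#' @param seed Integer seed for the ensemble noise.
#' @param sd_thresh Cauchy sifting-stop threshold (default 0.2).
#' @param max_sift Hard cap on sifting passes per IMF (default 50).
#' @return A list of class `eemd_config`.
#' @export
eemd_config <- function(ensemble_size = 30, noise_width = 0.2, max_imfs = 8,
                        seed = 1, sd_thresh = 0.2, max_sift = 50) {
  stopifnot(ensemble_size >= 1, noise_width >= 0, noise_width < 1,
            max_imfs >= 1)
  structure(list(ensemble_size = as.integer(ensemble_size),
                 noise_width = noise_width, max_imfs = as.integer(max_imfs),
                 seed = as.integer(seed), sd_thresh = sd_thresh,
                 max_sift = as.integer(max_sift)),
            class = "eemd_config")
}

.as_imf_set <- function(res, fs, span) {
  structure(list(imfs = lapply(res$imfs, as.numeric),
                 residual = as.numeric(res$residual),
                 fs = fs, source_span = span),
            class = "imf_set")
}

#' Empirical mode decomposition
#'
#' Plain EMD: iterative sifting with natural cubic-spline envelopes through
#' the local maxima/minima (two extrema mirrored at each end), subtracting
#' the mean envelope until the Cauchy criterion falls below `sd_thresh`.
#' Decomposition stops when the residual has fewer than three extrema or
#' `max_imfs` is reached. The IMFs plus residual reconstruct the input to
#' numerical precision.
#'
#' @param signal Numeric vector, length >= 16.
#' @param max_imfs Maximum number of IMFs.
#' @param fs Sampling rate carried into the result (default `NA`).
#' @param sd_thresh,max_sift Sifting-stop parameters.
#' @return An `imf_set`: list of IMFs (fast to slow), `residual`, `fs`,
#'   `source_span`.
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 512)
#' x <- sin(2 * pi * 25 * t) + 0.5 * sin(2 * pi * 2 * t)
#' d <- emd(x, max_imfs = 8)
#' max(abs(Reduce(`+`, d$imfs) + d$residual - x)) < 1e-8
emd <- function(signal, max_imfs = 8, fs = NA_real_, sd_thresh = 0.2,
                max_sift = 50) {
  if (length(signal) < 16) stop("signal must have at least 16 samples")
  res <- emd_cpp(as.numeric(signal), as.integer(max_imfs), sd_thresh,
                 as.integer(max_sift))
  .as_imf_set(res, fs, c(1L, length(signal)))
}

#' Ensemble empirical mode decomposition
#'
#' For each ensemble member, white Gaussian noise with standard deviation
#' `noise_width * sd(signal)` is added, the member is decomposed by [emd()],
#' and the IMFs are averaged index-wise across members (members that stop
#' early contribute zeros for missing indices). Deterministic for a fixed
#' `cfg$seed`.
#'
#' @param signal Numeric vector, length >= 16.
#' @param cfg An [eemd_config()].
#' @param fs Sampling rate carried into the result.
#' @return An `imf_set`.
#' @export
eemd <- function(signal, cfg = eemd_config(), fs = NA_real_) {
  if (length(signal) < 16) stop("signal must have at least 16 samples")
  res <- eemd_cpp(as.numeric(signal), cfg$ensemble_size, cfg$noise_width,
                  cfg$max_imfs, cfg$seed, cfg$sd_thresh, cfg$max_sift)
  .as_imf_set(res, fs, c(1L, length(signal)))
}

#' Cut a record into 10-second analysis windows
#'
#' Non-overlapping windows of `round(10 * fs)` samples; a trailing partial
#' window is dropped. Fetal and maternal R-peak annotations are re-indexed
#' to each window.
#'
#' @param rec An `aecg` record.
#' @param window_s Window length in seconds (default 10).
#' @return A list of windows, each with `signal`, `fs`, `fetal_rpeaks`,
#'   `maternal_rpeaks`, `fetal_clean`/`maternal_clean` (when present),
#'   `offset` (0-based sample offset of the window in the record) and
#'   `segment_index`.
#' @export
segment_10s <- function(rec, window_s = 10) {
  w <- round(window_s * rec$fs)
  n <- length(rec$signal)
  k <- n %/% w
  if (k == 0) return(list())
  lapply(seq_len(k), function(i) {
    a <- (i - 1L) * w + 1L
    b <- i * w
    reidx <- function(p) {
      p <- p[p >= a & p <= b]
      as.integer(p - a + 1L)
    }
    seg <- list(signal = rec$signal[a:b], fs = rec$fs,
                fetal_rpeaks = reidx(rec$fetal_rpeaks),
                maternal_rpeaks = reidx(rec$maternal_rpeaks),
                offset = a - 1L, segment_index = i)
    if (!is.null(rec$fetal_clean)) seg$fetal_clean <- rec$fetal_clean[a:b]
    if (!is.null(rec$maternal_clean)) seg$maternal_clean <- rec$maternal_clean[a:b]
    seg
  })
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual, %d samples%s\n",
              length(x$imfs), length(x$residual),
              if (is.na(x$fs)) "" else sprintf(" @ %g Hz", x$fs)))
  invisible(x)
}
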