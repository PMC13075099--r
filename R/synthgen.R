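#' Simulator case grid
#'
#' The 15 maternal/fetal parameter combinations emulated by the synthetic
#' generator, spanning maternal heart rates of 60--120 bpm, fetal heart rates
#' of 110--162 bpm and fetal-to-maternal amplitude ratios from 1:1.17 down to
#' 1:16, i.e. from a strong fetal signal to a nearly buried one.
#'
#' @return A data.frame with columns `case_id`, `m_hr`, `m_amp`, `f_hr`,
#'   `f_amp`, `ratio` (the fetal-to-maternal amplitude ratio as m_amp/f_amp)
#'   and `note`.
#' @export
#' @examples
#' table1_cases()[1, ]
table1_cases <- function() {
  df <- data.frame(
    case_id = 1:15,
    m_hr  = c(80, 75, 90, 70, 85, 72, 88, 65, 78, 92, 68, 84, 76, 82, 77),
    m_amp = c(0.35, 0.60, 0.75, 0.80, 0.80, 0.50, 0.65, 0.70, 0.45, 0.70,
              0.55, 0.45, 0.80, 0.40, 0.58),
    f_hr  = c(140, 152, 118, 145, 162, 135, 148, 160, 130, 125, 150, 142,
              155, 138, 144),
    f_amp = c(0.30, 0.20, 0.12, 0.07, 0.05, 0.25, 0.15, 0.09, 0.22, 0.08,
              0.18, 0.24, 0.06, 0.26, 0.19),
    ratio = c(1.17, 3.0, 6.3, 11.4, 16.0, 2.0, 4.3, 7.8, 2.0, 8.8, 3.1,
              1.9, 13.3, 1.5, 3.1),
    note = c("Fetal Upper Limit", "Light-Moderate Difficulty",
             "Long-tail Difficulty", "Low Fetal Amplitude",
             "High HR & Weak Amp", "Moderate Intensity", "Common Outpatient",
             "Strong Maternal/Weak Fetal", "Balanced Type",
             "Difficult Detection", "Moderate", "Slightly Weak Fetal",
             "Extremely Weak", "Fetal Approaching Maternal", "Daily Scenario"),
    stringsAsFactors = FALSE
  )
  df
}

# Beat morphology: five Gaussians (P, Q, R, S, T) with offsets and widths
# expressed as fractions of the RR interval, so fetal beats are
# proportionally narrower than maternal ones. Amplitudes are relative to the
# R wave and scaled by the case amplitude.
.beat_shape <- list(
  amp    = c(P = 0.15, Q = -0.12, R = 1.00, S = -0.22, T = 0.30),
  offset = c(P = -0.22, Q = -0.045, R = 0, S = 0.045, T = 0.30),
  width  = c(P = 0.040, Q = 0.014, R = 0.020, S = 0.016, T = 0.080)
)

# Run `expr` under a private, seeded RNG stream, restoring the caller's
# global RNG state afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

# One ECG-like channel: beats at jittered RR intervals, each a 5-Gaussian
# packet. Returns the waveform and the R-peak sample indices (1-based).
.synth_channel <- function(hr_bpm, amp, duration_s, fs, rr_jitter, amp_jitter) {
  rr0 <- 60 / hr_bpm
  n <- round(duration_s * fs)
  # R-peaks live on the sample grid; each RR interval is rounded to whole
  # samples so the jitter-free case is exactly periodic
  peaks <- c()
  p <- round(rr0 / 2 * fs) + 1L
  while (p <= n) {
    peaks <- c(peaks, p)
    p <- p + as.integer(round(fs * rr0 * (1 + rr_jitter * stats::rnorm(1))))
  }
  times <- (peaks - 1) / fs
  tgrid <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  sh <- .beat_shape
  for (tk in times) {
    a_k <- amp * (1 + amp_jitter * stats::rnorm(1))
    rr_k <- rr0
    # evaluate only on a local window for speed
    lo <- max(1L, floor((tk - 0.45 * rr_k) * fs) + 1L)
    hi <- min(n, ceiling((tk + 0.55 * rr_k) * fs) + 1L)
    if (lo > hi) next
    tt <- tgrid[lo:hi] - tk
    seg <- numeric(length(tt))
    for (w in seq_along(sh$amp)) {
      seg <- seg + sh$amp[[w]] *
        exp(-0.5 * ((tt - sh$offset[[w]] * rr_k) / (sh$width[[w]] * rr_k))^2)
    }
    x[lo:hi] <- x[lo:hi] + a_k * seg
  }
  list(signal = x, rpeaks = as.integer(peaks))
}

#' Generate one clean annotated synthetic abdominal ECG
#'
#' Builds maternal and fetal channels as trains of five-Gaussian (P, Q, R, S,
#' T) beats at the case heart rates, with multiplicative per-beat amplitude
#' jitter and RR-interval jitter, and sums them into an abdominal mixture.
#' R-peak sample indices of both components are carried as ground truth.
#'
#' @param params One row of [table1_cases()] (or a list with fields `case_id`,
#'   `m_hr`, `m_amp`, `f_hr`, `f_amp`).
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate in Hz (>= 250).
#' @param seed Integer seed; the same seed reproduces the record bit for bit.
#' @param rr_jitter Relative standard deviation of RR intervals (default 0.03).
#' @param amp_jitter Relative standard deviation of per-beat amplitude
#'   (default 0.05).
#' @return An object of class `aecg`: list with `signal`, `fs`,
#'   `fetal_rpeaks`, `maternal_rpeaks`, `fetal_clean`, `maternal_clean`,
#'   `subject_id`. Indices are 1-based.
#' @export
#' @examples
#' rec <- synth_clean_aecg(table1_cases()[1, ], duration_s = 10, fs = 500, seed = 1)
#' length(rec$fetal_rpeaks)
synth_clean_aecg <- function(params, duration_s, fs = 500, seed = 1,
                             rr_jitter = 0.03, amp_jitter = 0.05) {
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration_s must be positive")
  if (!is.numeric(fs) || fs < 250) stop("fs must be at least 250 Hz")
  params <- as.list(params)
  ch <- .with_seed(seed, list(
    m = .synth_channel(params$m_hr, params$m_amp, duration_s, fs, rr_jitter,
                       amp_jitter),
    f = .synth_channel(params$f_hr, params$f_amp, duration_s, fs, rr_jitter,
                       amp_jitter)
  ))
  m <- ch$m
  f <- ch$f
  structure(list(
    signal = m$signal + f$signal,
    fs = fs,
    fetal_rpeaks = f$rpeaks,
    maternal_rpeaks = m$rpeaks,
    fetal_clean = f$signal,
    maternal_clean = m$signal,
    subject_id = paste0("case", params$case_id)
  ), class = "aecg")
}

#' Noise augmentation specification
#'
#' EMG-like interference is Gaussian white noise bandpassed to
#' `emg_band` and scaled to `emg_scale` times the signal standard deviation;
#' baseline wander is the sum of sinusoids at `bw_freqs` scaled to `bw_scale`
#' times the signal standard deviation. The combined noise is then rescaled
#' by a single factor so the realized SNR equals `target_snr_db` exactly,
#' preserving the EMG-to-wander energy ratio.
#'
#' @param emg_band Two-element EMG passband in Hz (default c(20, 150)).
#' @param emg_scale EMG amplitude as a fraction of signal sd (default 0.1).
#' @param bw_freqs Baseline-wander frequencies in Hz (default c(0.2, 0.33)).
#' @param bw_scale Wander amplitude as a fraction of signal sd (default 0.18).
#' @param target_snr_db Overall SNR in dB enforced after mixing (default 10).
#' @param seed Integer seed for the noise realization.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(emg_band = c(20, 150), emg_scale = 0.1,
                       bw_freqs = c(0.2, 0.33), bw_scale = 0.18,
                       target_snr_db = 10, seed = 1) {
  stopifnot(length(emg_band) == 2, emg_band[1] < emg_band[2],
            emg_scale > 0, bw_scale > 0, is.finite(target_snr_db))
  structure(list(emg_band = emg_band, emg_scale = emg_scale,
                 bw_freqs = bw_freqs, bw_scale = bw_scale,
                 target_snr_db = target_snr_db, seed = seed),
            class = "noise_spec")
}

#' Add EMG noise and baseline wander at an exact SNR
#'
#' @param rec An `aecg` record with a clean (non-constant) signal.
#' @param spec A [noise_spec()].
#' @return The record with a noisy `signal`; annotations and clean components
#'   are unchanged.
#' @export
#' @examples
#' rec <- synth_clean_aecg(table1_cases()[1, ], 10, 500, seed = 1)
#' noisy <- add_noise(rec, noise_spec(seed = 2))
#' p_sig <- sum(rec$signal^2); p_noise <- sum((noisy$signal - rec$signal)^2)
#' 10 * log10(p_sig / p_noise) # 10 dB
add_noise <- function(rec, spec = noise_spec()) {
  x <- rec$signal
  if (stats::sd(x) == 0) stop("degenerate input: signal is constant")
  n <- length(x)
  fs <- rec$fs
  sdx <- stats::sd(x)

  hi <- min(spec$emg_band[2], 0.45 * fs) # keep band below Nyquist
  draws <- .with_seed(spec$seed, list(
    wn = stats::rnorm(n),
    ph = stats::runif(length(spec$bw_freqs))
  ))
  emg <- butter_bandpass_zerophase(draws$wn, fs, spec$emg_band[1], hi, order = 4)
  emg <- emg / stats::sd(emg) * (spec$emg_scale * sdx)

  tgrid <- (seq_len(n) - 1) / fs
  phases <- draws$ph * 2 * pi
  bw <- rowSums(sapply(seq_along(spec$bw_freqs), function(i)
    sin(2 * pi * spec$bw_freqs[i] * tgrid + phases[i])))
  bw <- bw / stats::sd(bw) * (spec$bw_scale * sdx)

  noise <- emg + bw
  # one global factor reconciles the per-source scales with the SNR target
  p_sig <- sum(x^2)
  p_noise <- sum(noise^2)
  alpha <- sqrt(p_sig / (p_noise * 10^(spec$target_snr_db / 10)))
  rec$signal <- x + alpha * noise
  rec
}

#' @export
print.aecg <- function(x, ...) {
  cat(sprintf("<aecg> %s: %d samples @ %g Hz (%.1f s), %d fetal / %d maternal R-peaks%s\n",
              x$subject_id, length(x$signal), x$fs, length(x$signal) / x$fs,
              length(x$fetal_rpeaks), length(x$maternal_rpeaks),
              if (!is.null(x$fetal_clean)) ", clean components kept" else ""))
  invisible(x)
}
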