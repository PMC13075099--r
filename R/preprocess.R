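#' Double the sampling rate by polyphase resampling
#'
#' Upsamples by 2 and downsamples by 1 through a Kaiser-windowed anti-imaging
#' low-pass, the standard polyphase structure. Annotation indices on the
#' original grid map to the doubled grid with [map_indices_2x()].
#'
#' @param signal Numeric vector.
#' @param fs_in Input sampling rate in Hz.
#' @return List with `signal` (length exactly `2 * length(signal)`) and `fs`
#'   (`2 * fs_in`).
#' @export
resample_2x <- function(signal, fs_in) {
  if (length(signal) == 0) stop("empty signal")
  if (!is.numeric(fs_in) || fs_in <= 0) stop("fs_in must be positive")
  n <- length(signal)
  # zero-stuff, then zero-phase FIR low-pass at the original Nyquist
  up <- numeric(2L * n)
  up[seq(1L, 2L * n, by = 2L)] <- signal
  ord <- 10L * 2L       # 10 taps per polyphase branch
  h <- signal::fir1(2L * ord, 1 / 2, type = "low",
                    window = signal::kaiser(2L * ord + 1L, beta = 5))
  h <- 2 * h            # restore passband gain lost to zero-stuffing
  pad <- length(h)
  ext <- c(rev(up[seq_len(pad)]), up, rev(up[(2L * n - pad + 1L):(2L * n)]))
  y <- stats::filter(ext, h, sides = 2L)
  y <- as.numeric(y[(pad + 1L):(pad + 2L * n)])
  list(signal = y, fs = 2 * fs_in)
}

#' Map 1-based annotation indices to the doubled sampling grid
#'
#' A sample at index `i` (time `(i-1)/fs`) lands at index `2*i - 1` on the
#' doubled grid, preserving its physical time.
#'
#' @param idx Integer vector of 1-based sample indices.
#' @return Integer vector of indices on the doubled grid.
#' @export
map_indices_2x <- function(idx) as.integer(2L * idx - 1L)

# scipy-style initial filter state (steady state for a unit step), so the
# forward-backward pass starts without a switch-on transient
.lfilter_zi <- function(b, a) {
  nfilt <- max(length(a), length(b))
  a <- c(a, numeric(nfilt - length(a)))
  b <- c(b, numeric(nfilt - length(b)))
  b <- b / a[1]
  a <- a / a[1]
  if (nfilt == 1) return(numeric(0))
  comp <- rbind(-a[-1], cbind(diag(nfilt - 2), 0))
  if (nfilt == 2) comp <- matrix(-a[2], 1, 1)
  IminusA <- diag(nfilt - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

# zero-phase IIR filtering: odd-reflection padding plus steady-state initial
# conditions, forward then reverse; generous padding lets filter transients
# ring out before the record starts
.filtfilt_pad <- function(b, a, x, pad_len = NULL) {
  n <- length(x)
  nf <- max(3L * (max(length(a), length(b)) - 1L),
            if (is.null(pad_len)) 0L else as.integer(pad_len))
  nf <- min(nf, n - 2L)
  if (n <= 3L * (max(length(a), length(b)) - 1L) + 1L)
    stop("signal too short for zero-phase filtering")
  pre <- 2 * x[1] - x[(nf + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - nf)]
  ext <- c(pre, x, post)
  zi <- .lfilter_zi(b, a)
  y <- .lfilter(b, a, ext, zi * ext[1])
  y <- rev(.lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(nf + 1L):(nf + n)]
}

# direct-form II transposed IIR filter with initial state
.lfilter <- function(b, a, x, zi) {
  nfilt <- max(length(a), length(b))
  a <- c(a, numeric(nfilt - length(a)))
  b <- c(b, numeric(nfilt - length(b)))
  b <- b / a[1]
  a <- a / a[1]
  lfilter_cpp(b, a, x, zi)
}

#' 50 Hz IIR notch filter
#'
#' Second-order IIR notch (biquad) centred at 50 Hz, applied zero-phase,
#' removing power-line interference while leaving neighbouring ECG content
#' within 1 dB.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz; must exceed 100 so 50 Hz is below Nyquist.
#' @param q Quality factor (centre frequency over -3 dB bandwidth), default 30.
#' @return Filtered signal, same length.
#' @export
notch_50 <- function(signal, fs, q = 30) {
  if (fs <= 100) stop("fs must exceed 100 Hz for a 50 Hz notch")
  w0 <- 2 * pi * 50 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  .filtfilt_pad(b / a[1], a / a[1], signal)
}

#' Zero-phase Butterworth bandpass
#'
#' Designs an order-`order` Butterworth bandpass and applies it forward and
#' backward (squaring the magnitude response, cancelling the phase). Used
#' with (0.1, 100) for preprocessing, (8, 45) for reference fetal-lead
#' filtering and (10, 60) for the refined and final fetal estimates.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Filter order of the one-way design (default 4).
#' @return Filtered signal, same length.
#' @export
butter_bandpass_zerophase <- function(signal, fs, lo, hi, order = 4) {
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop("hi must be below the Nyquist frequency")
  # cascade of second-order sections: a transfer-function realization of a
  # wide-band design (e.g. 0.1-100 Hz at 1000 Hz) is numerically singular,
  # biquads are not
  sos <- .butter_sos_bandpass(order, lo, hi, fs)
  out <- signal
  for (sec in sos) out <- .filtfilt_pad(sec$b, sec$a, out)
  out
}

# Butterworth bandpass as biquads, built from the analog prototype with a
# per-pole bilinear transform so the order-2n polynomial is never formed.
# Each section holds one conjugate digital pole pair and the zero pair
# (+1, -1), normalized to unit gain at the (warped) centre frequency.
.butter_sos_bandpass <- function(order, lo, hi, fs) {
  wl <- 2 * fs * tan(pi * lo / fs) # pre-warped analog edges
  wh <- 2 * fs * tan(pi * hi / fs)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # unit LP poles
  # lowpass-to-bandpass: each prototype pole spawns two analog poles
  bp <- proto * bw / 2
  apoles <- c(bp + sqrt(bp^2 - w0^2), bp - sqrt(bp^2 - w0^2))
  zpoles <- (2 * fs + apoles) / (2 * fs - apoles) # bilinear
  upper <- zpoles[Im(zpoles) >= 0]
  upper <- upper[order(-Mod(upper))]
  wc <- 2 * atan(w0 / (2 * fs)) # centre on the digital grid, rad/sample
  zc <- exp(1i * wc)
  # each section consumes one zero pair; pairing the double zero at +1 with
  # the poles nearest +1 (and -1 likewise) keeps every biquad well behaved
  avail <- c(pos = order, neg = order)
  sections <- lapply(upper, function(pk) {
    a <- c(1, -2 * Re(pk), Mod(pk)^2)
    prefer <- if (Mod(pk - 1) <= Mod(pk + 1)) "pos" else "neg"
    other <- setdiff(c("pos", "neg"), prefer)
    if (avail[prefer] >= 2) {
      avail[prefer] <<- avail[prefer] - 2
      b <- if (prefer == "pos") c(1, -2, 1) else c(1, 2, 1)
    } else if (avail[other] >= 2) {
      avail[other] <<- avail[other] - 2
      b <- if (other == "pos") c(1, -2, 1) else c(1, 2, 1)
    } else {
      avail <<- avail - 1
      b <- c(1, 0, -1)
    }
    g <- Mod(sum(b * zc^-(0:2)) / sum(a * zc^-(0:2)))
    list(b = b / g, a = a)
  })
  sections
}

#' Standard preprocessing chain
#'
#' 50 Hz notch followed by a fourth-order 0.1--100 Hz zero-phase Butterworth
#' bandpass. Annotations pass through unchanged (zero-phase filtering does
#' not move R-peaks).
#'
#' @param rec An `aecg` record with `fs >= 250`.
#' @param notch_q Notch quality factor (default 30).
#' @return The record with filtered `signal`.
#' @export
preprocess_standard <- function(rec, notch_q = 30) {
  if (rec$fs < 250) stop("fs must be at least 250 Hz")
  x <- notch_50(rec$signal, rec$fs, q = notch_q)
  rec$signal <- butter_bandpass_zerophase(x, rec$fs, 0.1, 100, order = 4)
  rec
}
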