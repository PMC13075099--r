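#' Extraction pipeline configuration
#'
#' @param n1 IMFs kept in stage 1 (default 2).
#' @param n2 IMFs kept in stage 2 (default 1).
#' @param eemd An [eemd_config()].
#' @param refine_band Passband in Hz for the refinement and final filters
#'   (default c(10, 60)).
#' @param template_halfwidth Maternal template half width in seconds
#'   (default 0.3; additionally clipped so adjacent beat windows overlap at
#'   most half of the shortest RR interval).
#' @param min_maternal_rr Minimum maternal RR in seconds (default 0.5,
#'   i.e. a maternal rate of at most 120 bpm).
#' @param min_fetal_rr Minimum fetal RR in seconds (default 0.3).
#' @param selection_mode `"cnn"`, `"auto"` (heuristic energy/correlation
#'   ranking) or `"oracle"` (requires fetal ground truth).
#' @param stage2_combine `"add"` (default) to add the stage-2 component to
#'   the refined estimate, or `"replace"` to substitute it.
#' @param stage2_input `"subtraction_residual"` (default) decomposes what the
#'   stage-1 selection left behind (`residual - initial`), which still holds
#'   low-amplitude fetal energy spread beyond the selected IMFs;
#'   `"refined_minus_initial"` decomposes the difference between the refined
#'   and initial estimates instead.
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(n1 = 2, n2 = 1, eemd = eemd_config(),
                              refine_band = c(10, 60),
                              template_halfwidth = 0.3,
                              min_maternal_rr = 0.5, min_fetal_rr = 0.3,
                              selection_mode = c("cnn", "auto", "oracle"),
                              stage2_combine = c("add", "replace"),
                              stage2_input = c("subtraction_residual",
                                               "refined_minus_initial")) {
  selection_mode <- match.arg(selection_mode)
  stage2_combine <- match.arg(stage2_combine)
  stage2_input <- match.arg(stage2_input)
  stopifnot(n1 >= 1, n2 >= 1, n1 + n2 <= eemd$max_imfs)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), eemd = eemd,
                 refine_band = refine_band,
                 template_halfwidth = template_halfwidth,
                 min_maternal_rr = min_maternal_rr,
                 min_fetal_rr = min_fetal_rr,
                 selection_mode = selection_mode,
                 stage2_combine = stage2_combine,
                 stage2_input = stage2_input),
            class = "extraction_config")
}

# integrate-and-threshold QRS detector: bandpass -> derivative -> squaring ->
# moving-window integration -> amplitude threshold with refractory period,
# then peak refinement on the bandpassed signal
.qrs_detect <- function(x, fs, band, min_rr_s) {
  bp <- butter_bandpass_zerophase(x, fs, band[1], band[2], order = 3)
  d <- c(0, diff(bp))
  sq <- d^2
  w <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.3 * stats::quantile(integ, 0.95, names = FALSE)
  min_dist <- round(min_rr_s * fs)
  rough <- .peaks_above(integ, thr, min_dist)
  # snap each detection to the local |bp| maximum (+/- 100 ms)
  half <- round(0.1 * fs)
  peaks <- vapply(rough, function(p) {
    a <- max(1L, as.integer(p - half))
    b <- min(length(bp), as.integer(p + half))
    a + which.max(abs(bp[a:b])) - 1L
  }, integer(1))
  sort(unique(peaks))
}

#' Detect maternal R-peaks
#'
#' Primary detection is a multi-stage integrate-and-threshold QRS detector
#' (bandpass, derivative, squaring, moving integration, adaptive threshold).
#' Detection is declared failed when fewer than `duration * 40/60` peaks are
#' found or the RR spread is implausible (coefficient of variation above
#' 0.5); a fallback then keeps local maxima of the absolute signal above an
#' adaptive amplitude threshold with a minimum RR of `min_rr_s`.
#'
#' @param signal Preprocessed abdominal signal.
#' @param fs Sampling rate in Hz.
#' @param min_rr_s Minimum maternal RR in seconds (default 0.5).
#' @return Integer vector of 1-based peak indices with attribute `method`
#'   (`"primary"` or `"fallback"`); empty for a flat signal.
#' @export
detect_maternal_rpeaks <- function(signal, fs, min_rr_s = 0.5) {
  if (stats::sd(signal) == 0) return(structure(integer(0), method = "none"))
  peaks <- .qrs_detect(signal, fs, band = c(5, 25), min_rr_s = min_rr_s)
  dur <- length(signal) / fs
  ok <- length(peaks) >= dur * 40 / 60
  if (ok && length(peaks) >= 3) {
    rr <- diff(peaks)
    ok <- stats::sd(rr) / mean(rr) <= 0.5
  }
  if (ok) return(structure(peaks, method = "primary"))
  f <- abs(signal)
  thr <- 0.5 * stats::quantile(f, 0.95, names = FALSE)
  structure(.peaks_above(f, thr, round(min_rr_s * fs)), method = "fallback")
}

#' Coherent-average maternal template
#'
#' Elementwise mean over fixed-length windows centred at each maternal
#' R-peak; beats whose window exits the record are skipped.
#'
#' @param signal Preprocessed abdominal signal.
#' @param rpeaks Maternal R-peak indices.
#' @param halfwidth Half window width in samples; window length is
#'   `2 * halfwidth + 1`.
#' @return Numeric template of length `2 * halfwidth + 1` with attribute
#'   `n_beats` (number of averaged beats).
#' @export
build_maternal_template <- function(signal, rpeaks, halfwidth) {
  n <- length(signal)
  usable <- rpeaks[rpeaks - halfwidth >= 1 & rpeaks + halfwidth <= n]
  if (length(usable) < 2) stop("degenerate template: fewer than 2 usable beats")
  acc <- numeric(2 * halfwidth + 1)
  for (p in usable) acc <- acc + signal[(p - halfwidth):(p + halfwidth)]
  structure(acc / length(usable), n_beats = length(usable))
}

#' Subtract the maternal contribution
#'
#' Places the template at every detected maternal R-peak (overlapping
#' placements sum linearly), forming a maternal reconstruction track that is
#' subtracted from the signal.
#'
#' @param signal Preprocessed abdominal signal.
#' @param template Template from [build_maternal_template()].
#' @param rpeaks Maternal R-peak indices.
#' @return Residual signal, same length as the input.
#' @export
subtract_maternal <- function(signal, template, rpeaks) {
  n <- length(signal)
  if (length(rpeaks) == 0) return(signal)
  hw <- (length(template) - 1L) %/% 2L
  track <- numeric(n)
  for (p in rpeaks) {
    a <- max(1L, p - hw)
    b <- min(n, p + hw)
    ta <- a - (p - hw) + 1L
    track[a:b] <- track[a:b] + template[ta:(ta + (b - a))]
  }
  signal - track
}

#' Sum the k highest-scoring IMFs
#'
#' Ties are broken toward the lower IMF index (the faster component).
#'
#' @param imfs An `imf_set` or list of numeric vectors.
#' @param scores One score per IMF.
#' @param k How many IMFs to keep.
#' @return Numeric vector: the sum of the selected IMFs.
#' @export
select_top_k <- function(imfs, scores, k) {
  waves <- if (inherits(imfs, "imf_set")) imfs$imfs else imfs
  if (length(scores) != length(waves)) stop("one score per IMF required")
  if (k > length(waves)) {
    warning("k exceeds the number of IMFs; using all")
    k <- length(waves)
  }
  sel <- order(-scores, seq_along(scores))[seq_len(k)]
  Reduce(`+`, waves[sel])
}

#' Heuristic IMF scores (energy and correlation)
#'
#' Scores each IMF by the product of its spectral-energy fraction inside
#' 8--45 Hz (the fetal QRS band) and the absolute Pearson correlation with
#' the 8--45 Hz filtered reference signal, normalized to a maximum of 1.
#' This is the fixed-rule automatic ranking used as a baseline against the
#' learned scorer.
#'
#' @param imfs An `imf_set` with known `fs`.
#' @param reference The pre-subtraction abdominal signal over the same span.
#' @return Numeric scores in \[0, 1\].
#' @export
auto_select_scores <- function(imfs, reference) {
  fs <- imfs$fs
  if (is.na(fs)) stop("imf_set must carry a sampling rate")
  ref_f <- butter_bandpass_zerophase(reference, fs, 8, min(45, 0.45 * fs), 4)
  sc <- vapply(imfs$imfs, function(v) {
    sp <- Mod(stats::fft(v))^2
    nf <- length(sp) %/% 2
    freqs <- (seq_len(nf) - 1) * fs / length(sp)
    inband <- sum(sp[seq_len(nf)][freqs >= 8 & freqs <= 45])
    total <- sum(sp[seq_len(nf)])
    efrac <- if (total > 0) inband / total else 0
    r <- if (stats::sd(v) > 0 && stats::sd(ref_f) > 0) abs(stats::cor(v, ref_f)) else 0
    efrac * r
  }, numeric(1))
  if (max(sc) > 0) sc / max(sc) else sc
}

#' Oracle IMF scores from ground truth
#'
#' Absolute Pearson correlation of each IMF with the known clean fetal
#' component; available for synthetic records only and used as an
#' upper-bound selection reference.
#'
#' @param imfs An `imf_set` or list of numeric vectors.
#' @param fetal_truth Clean fetal component over the same span.
#' @return Numeric scores in \[0, 1\].
#' @export
oracle_select_scores <- function(imfs, fetal_truth) {
  if (is.null(fetal_truth)) stop("ground-truth fetal component unavailable")
  waves <- if (inherits(imfs, "imf_set")) imfs$imfs else imfs
  vapply(waves, function(v) {
    if (stats::sd(v) == 0 || stats::sd(fetal_truth) == 0) return(0)
    abs(stats::cor(v, fetal_truth))
  }, numeric(1))
}

# segment boundaries for stage-wise decomposition: full 10 s windows plus a
# trailing remainder when it is long enough to decompose
.stage_spans <- function(n, fs, window_s = 10) {
  w <- round(window_s * fs)
  k <- n %/% w
  spans <- lapply(seq_len(k), function(i) c((i - 1L) * w + 1L, i * w))
  rem <- n - k * w
  if (rem >= 16) spans[[length(spans) + 1L]] <- c(k * w + 1L, n)
  spans
}

# decompose a track segment-wise, score per selection mode, keep top k
.stage_select <- function(track, fs, cfg, model, mode, reference, truth,
                          seed_tag) {
  n <- length(track)
  out <- numeric(n)
  spans <- .stage_spans(n, fs)
  all_scores <- list()
  all_imfs <- list()
  for (si in seq_along(spans)) {
    a <- spans[[si]][1]
    b <- spans[[si]][2]
    ecfg <- cfg$eemd
    ecfg$seed <- derive_seed(cfg$eemd$seed, paste0(seed_tag, ":", si))
    dec <- eemd(track[a:b], ecfg, fs = fs)
    if (length(dec$imfs) == 0) {
      out[a:b] <- track[a:b]
      next
    }
    scores <- switch(mode,
      cnn = score_imfs(model, dec),
      auto = auto_select_scores(dec, reference[a:b]),
      oracle = oracle_select_scores(dec, truth[a:b]))
    k <- min(if (seed_tag == "stage1") cfg$n1 else cfg$n2, length(dec$imfs))
    out[a:b] <- select_top_k(dec, scores, k)
    all_scores[[si]] <- scores
    all_imfs[[si]] <- dec
  }
  list(track = out, scores = all_scores, imfs = all_imfs)
}

#' Extract the fetal ECG from a single abdominal channel
#'
#' The full pipeline: preprocessing, maternal R-peak detection,
#' coherent-average template subtraction, a first EEMD whose `n1`
#' top-scoring IMFs form the initial fetal estimate, 10--60 Hz refinement, a
#' second EEMD on the refinement residual whose top `n2` IMFs are added
#' back, and a final zero-phase 10--60 Hz bandpass with fetal R-peak
#' detection. Records longer than 10 s are decomposed in consecutive 10 s
#' windows with the same configuration.
#'
#' @param x An `aecg` record, or a numeric signal (then `fs` is required).
#' @param fs Sampling rate in Hz (taken from the record when `x` is `aecg`).
#' @param model A trained `imf_classifier` (required for
#'   `selection_mode = "cnn"`).
#' @param cfg An [extraction_config()].
#' @param preprocessed Set TRUE when `x` already went through
#'   [preprocess_standard()].
#' @return A list of class `extraction_result`: `fecg`, `fetal_rpeaks`,
#'   `stage1_estimate`, `refined`, `stage2_component`, `stage1_scores`,
#'   `stage2_scores`, `maternal_rpeaks`, `template`, `residual` (the
#'   post-subtraction track) and `fs`.
#' @export
extract_fecg <- function(x, fs = NULL, model = NULL,
                         cfg = extraction_config(), preprocessed = FALSE) {
  if (inherits(x, "aecg")) {
    rec <- x
  } else {
    if (is.null(fs)) stop("fs is required when x is a plain signal")
    rec <- structure(list(signal = as.numeric(x), fs = fs,
                          fetal_rpeaks = integer(0),
                          maternal_rpeaks = integer(0),
                          subject_id = "anonymous"), class = "aecg")
  }
  fs <- rec$fs
  if (cfg$selection_mode == "cnn" && is.null(model))
    stop("selection_mode 'cnn' requires a trained model")
  if (cfg$selection_mode == "oracle" && is.null(rec$fetal_clean))
    stop("selection_mode 'oracle' requires a record with fetal_clean ground truth")

  pre <- if (preprocessed) rec else preprocess_standard(rec)
  sig <- pre$signal

  m_peaks <- detect_maternal_rpeaks(sig, fs, cfg$min_maternal_rr)
  if (length(m_peaks) < 2)
    stop("extraction aborted at stage maternal-detection: no maternal R-peaks found")

  hw <- round(cfg$template_halfwidth * fs)
  min_rr <- min(diff(m_peaks))
  hw <- min(hw, floor(0.375 * min_rr))
  template <- build_maternal_template(sig, m_peaks, hw)
  resid <- subtract_maternal(sig, template, m_peaks)

  truth <- rec$fetal_clean
  s1 <- .stage_select(resid, fs, cfg, model, cfg$selection_mode, sig, truth,
                      "stage1")
  initial <- s1$track
  initial_rpeaks <- .qrs_detect(initial, fs, band = c(8, min(45, 0.45 * fs)),
                                min_rr_s = cfg$min_fetal_rr)

  refined <- butter_bandpass_zerophase(initial, fs, cfg$refine_band[1],
                                       min(cfg$refine_band[2], 0.45 * fs), 4)
  r2 <- if (cfg$stage2_input == "subtraction_residual") resid - initial
        else refined - initial
  s2 <- .stage_select(r2, fs, cfg, model, cfg$selection_mode, sig, truth,
                      "stage2")
  combined <- if (cfg$stage2_combine == "add") refined + s2$track else s2$track
  fecg <- butter_bandpass_zerophase(combined, fs, cfg$refine_band[1],
                                    min(cfg$refine_band[2], 0.45 * fs), 4)
  f_peaks <- .qrs_detect(fecg, fs, band = c(8, min(45, 0.45 * fs)),
                         min_rr_s = cfg$min_fetal_rr)

  structure(list(fecg = fecg, fetal_rpeaks = f_peaks,
                 stage1_estimate = initial, initial_rpeaks = initial_rpeaks,
                 refined = refined,
                 stage2_component = s2$track, stage1_scores = s1$scores,
                 stage2_scores = s2$scores, maternal_rpeaks = m_peaks,
                 template = as.numeric(template), residual = resid, fs = fs),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("<extraction_result> %d samples @ %g Hz, %d fetal R-peaks detected\n",
              length(x$fecg), x$fs, length(x$fetal_rpeaks)))
  invisible(x)
}
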